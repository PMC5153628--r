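#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability that
#' a random positive outscores a random negative, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length.
#' @return Scalar in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: thresholds sweep the distinct score values from
#' high to low, and each recall increment is weighted by the precision at
#' that threshold (no interpolation between points).
#'
#' @inheritParams auc_score
#' @return Scalar in (0, 1].
#' @export
aupr_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  # thresholds at the last index of each tied score block
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[block_end] / k[block_end]
  rec <- tp[block_end] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Chemical-wise cross-validation folds
#'
#' Partitions the chemicals into k folds of sizes differing by at most one,
#' independently in each round. Splitting on chemicals (whole columns held
#' out) evaluates prediction for chemicals with no training interactions —
#' the cold-start setting — rather than the easier hidden-entry setting.
#'
#' @param n_chemicals number of chemicals.
#' @param k folds per round.
#' @param rounds number of independent rounds.
#' @param seed integer seed.
#' @return A list of rounds; each round is a list of k integer vectors of
#'   test-chemical indices forming a partition of \code{1:n_chemicals}.
#' @export
chemical_cv_split <- function(n_chemicals, k = 5, rounds = 1, seed = 1L) {
  stopifnot(k >= 2, k <= n_chemicals, rounds >= 1)
  set.seed(seed)
  lapply(seq_len(rounds), function(rd) {
    perm <- sample.int(n_chemicals)
    fold_of <- rep_len(seq_len(k), n_chemicals)
    lapply(seq_len(k), function(f) sort(perm[fold_of == f]))
  })
}

#' True positive rate among the top r percent of predictions
#'
#' The fraction of a chemical's true targets ranked within the top
#' \code{round(n_targets * r / 100)} positions of its prediction vector
#' (for 3500 targets and r = 1 the cutoff is rank 35). Rank ties take the
#' worst rank, so the metric never benefits from tied scores.
#'
#' @param scores prediction scores over all targets for one chemical.
#' @param true_targets indices (or logical mask) of the true targets.
#' @param r_percent cutoff percentage in (0, 100].
#' @return Scalar in [0, 1].
#' @export
tpr_at_top_percent <- function(scores, true_targets, r_percent) {
  stopifnot(r_percent > 0, r_percent <= 100)
  if (is.logical(true_targets)) true_targets <- which(true_targets)
  stopifnot(length(true_targets) >= 1)
  # the top-r% always contains at least the top-ranked prediction
  cutoff <- max(1L, round(length(scores) * r_percent / 100))
  rk <- rank(-scores, ties.method = "max")
  mean(rk[true_targets] <= cutoff)
}

#' Paired significance test between per-fold metrics
#'
#' Paired t-test on fold-wise metric differences, the standard way to
#' compare two methods run on identical cross-validation folds. A
#' zero-variance difference vector (identical fold metrics) is reported as
#' degenerate rather than raising an error.
#'
#' @param per_fold_a,per_fold_b equal-length numeric vectors of per-fold
#'   metrics.
#' @param alpha significance level for the convenience flag.
#' @return List with \code{p_value}, \code{statistic}, \code{mean_diff},
#'   \code{significant}, \code{degenerate}.
#' @export
fold_significance <- function(per_fold_a, per_fold_b, alpha = 0.05) {
  stopifnot(length(per_fold_a) == length(per_fold_b),
            length(per_fold_a) >= 2)
  d <- per_fold_a - per_fold_b
  if (stats::sd(d) == 0)
    return(list(p_value = NA_real_, statistic = NA_real_,
                mean_diff = mean(d), significant = FALSE, degenerate = TRUE))
  tt <- stats::t.test(per_fold_a, per_fold_b, paired = TRUE)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       mean_diff = mean(d), significant = tt$p.value < alpha,
       degenerate = FALSE)
}

# fit with the given columns blanked and cold-started; returns the
# probability matrix
fit_with_heldout_chemicals <- function(data, M, N, config, test_cols,
                                       J = 5, v = 0.5) {
  R_train <- int_mat(data)
  R_train[, test_cols] <- 0
  fit <- cosine_fit(interaction_dataset(R_train), M, N, config)
  fit <- apply_cold_start(fit, chem_sim = N, new_chemicals = test_cols,
                          J = J, v = v)
  predict(fit)
}

#' Chemical-wise cross-validation benchmark
#'
#' For each fold, the test chemicals' interaction columns are zeroed during
#' training (their weights fall to the baseline), the model is refit, the
#' held-out chemicals receive the weighted-profile cold start, and AUC and
#' AUPR are computed over all (test chemical, target) pairs against the
#' hidden labels. Metrics are computed per fold and then averaged.
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param target_sim,chem_sim similarity matrices aligned with \code{data}.
#' @param config a \code{\link{cosine_config}}.
#' @param k folds per round; \code{rounds} rounds are run.
#' @param rounds number of cross-validation rounds.
#' @param seed integer seed for the fold assignment.
#' @param J,v cold-start parameters (see \code{\link{apply_cold_start}}).
#' @return A list of class \code{eval_report} with \code{per_fold}
#'   (data.frame: round, fold, auc, aupr) and \code{aggregate}
#'   (means and sds).
#' @export
run_chemical_cv <- function(data, target_sim, chem_sim,
                            config = cosine_config(),
                            k = 5, rounds = 1, seed = 1L,
                            J = 5, v = 0.5) {
  R <- int_mat(data)
  M <- sim_mat(target_sim); N <- sim_mat(chem_sim)
  splits <- chemical_cv_split(ncol(R), k, rounds, seed)
  rows <- list()
  for (rd in seq_along(splits)) {
    for (f in seq_along(splits[[rd]])) {
      test_cols <- splits[[rd]][[f]]
      P <- fit_with_heldout_chemicals(data, M, N, config, test_cols, J, v)
      sc <- as.vector(P[, test_cols])
      lb <- as.vector(R[, test_cols])
      if (sum(lb) == 0 || sum(lb) == length(lb)) {
        warning(sprintf("round %d fold %d is single-class; metrics are NA",
                        rd, f))
        fold_auc <- NA_real_; fold_aupr <- NA_real_
      } else {
        fold_auc <- auc_score(sc, lb); fold_aupr <- aupr_score(sc, lb)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(round = rd, fold = f, auc = fold_auc, aupr = fold_aupr)
    }
  }
  per_fold <- do.call(rbind, rows)
  new_eval_report("chemical_cv", per_fold,
                  c(auc_mean = mean(per_fold$auc, na.rm = TRUE),
                    auc_sd = stats::sd(per_fold$auc, na.rm = TRUE),
                    aupr_mean = mean(per_fold$aupr, na.rm = TRUE),
                    aupr_sd = stats::sd(per_fold$aupr, na.rm = TRUE)),
                  list(k = k, rounds = rounds, seed = seed, J = J, v = v,
                       config = config))
}

#' Leave-one-out Top-1 benchmark
#'
#' For every chemical with at least one known interaction, all of its
#' interactions are hidden, the model predicts its targets from scratch
#' (cold start), and the chemical counts as a success when the top-ranked
#' target is one of its hidden true targets (ties resolved pessimistically:
#' a tie at the top only counts if every tied score belongs to a true
#' target). Returns the success percentage.
#'
#' In \code{retrain = "full"} mode the model is refit for every left-out
#' chemical (the reference semantics). In \code{retrain = "fast"} mode the
#' model is fit once per fold-free training matrix with all evaluated
#' columns zeroed jointly and only the cold-start row is recomputed per
#' chemical; this is cheaper but not identical, so the mode is always
#' recorded in the report.
#'
#' @inheritParams run_chemical_cv
#' @param retrain \code{"full"} or \code{"fast"}.
#' @return An \code{eval_report} with per-chemical rows (\code{chemical},
#'   \code{top1_correct}) and aggregate \code{top1_percent}.
#' @export
loocv_top1 <- function(data, target_sim, chem_sim,
                       config = cosine_config(),
                       J = 5, v = 0.5, retrain = c("full", "fast")) {
  retrain <- match.arg(retrain)
  R <- int_mat(data)
  M <- sim_mat(target_sim); N <- sim_mat(chem_sim)
  eval_cols <- which(colSums(R) >= 1)
  correct <- logical(length(eval_cols))
  if (retrain == "fast") {
    R0 <- R; R0[, eval_cols] <- 0
    base_fit <- cosine_fit(interaction_dataset(R0), M, N, config)
  }
  for (idx in seq_along(eval_cols)) {
    j <- eval_cols[idx]
    if (retrain == "full") {
      P <- fit_with_heldout_chemicals(data, M, N, config, j, J, v)
    } else {
      fit_j <- apply_cold_start(base_fit, chem_sim = N, new_chemicals = j,
                                J = J, v = v)
      P <- predict(fit_j)
    }
    rk <- rank(-P[, j], ties.method = "max")
    correct[idx] <- any(rk[R[, j] == 1] == 1)
  }
  per <- data.frame(chemical = eval_cols, top1_correct = correct)
  new_eval_report("loocv_top1", per,
                  c(top1_percent = 100 * mean(correct)),
                  list(J = J, v = v, retrain = retrain, config = config))
}

lt_bin_breaks <- c(0, 5, 10, 15, 20, Inf)
lt_bin_labels <- c("1-5", "6-10", "11-15", "16-20", ">20")

#' Stratify cold-start chemicals for the recovery benchmark
#'
#' Assigns each single-target chemical to one ligands-per-target bin
#' (1-5, 6-10, 11-15, 16-20, >20 ligands) and one maximum-chemical-
#' similarity bin of width 0.1, then halves every stratum into test and
#' training subsets of approximately equal size.
#'
#' @param cold_info data.frame as produced by
#'   \code{\link{make_coldstart_fixture}} (columns \code{chemical},
#'   \code{ligands_per_target}, \code{max_chem_similarity}).
#' @param seed integer seed for the halving.
#' @return \code{cold_info} with added columns \code{lt_bin},
#'   \code{mcs_bin}, and \code{role} ("test" or "train"), the halving done
#'   within each ligands-per-target bin.
#' @export
coldstart_stratify <- function(cold_info, seed = 1L) {
  stopifnot(all(c("chemical", "ligands_per_target", "max_chem_similarity")
                %in% names(cold_info)))
  out <- cold_info
  out$lt_bin <- as.character(cut(out$ligands_per_target, lt_bin_breaks,
                                 labels = lt_bin_labels, right = TRUE))
  mcs_lo <- pmin(floor(out$max_chem_similarity * 10) / 10, 0.9)
  out$mcs_bin <- sprintf("[%.1f,%.1f)", mcs_lo, mcs_lo + 0.1)
  set.seed(seed)
  out$role <- "train"
  for (b in unique(out$lt_bin)) {
    idx <- which(out$lt_bin == b)
    n_test <- ceiling(length(idx) / 2)
    out$role[idx[sample.int(length(idx))][seq_len(n_test)]] <- "test"
  }
  out
}

new_eval_report <- function(protocol, per_fold, aggregate, settings) {
  structure(list(protocol = protocol, per_fold = per_fold,
                 aggregate = aggregate, settings = settings),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$protocol, "\n")
  agg <- x$aggregate
  for (nm in names(agg)) cat(sprintf("  %s = %.4f\n", nm, agg[[nm]]))
  invisible(x)
}
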