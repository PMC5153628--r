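#' Read a configuration file into a cosine_config
#'
#' Accepts a YAML (or flat \code{key: value}) file whose keys match the
#' arguments of \code{\link{cosine_config}}; unknown keys are rejected so
#' typos never silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A \code{\link{cosine_config}}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(cosine_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(cosine_config, vals)
}

#' Write a resolved configuration next to run outputs
#'
#' @param config a \code{\link{cosine_config}}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  # full double precision so a reloaded config reproduces runs exactly
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Save and load a fitted model as plain text
#'
#' The checkpoint directory holds \code{F.tsv} and \code{G.tsv} (latent
#' factors with identifiers), \code{config.yaml} (resolved configuration)
#' and, when present, the training state matrices \code{W.tsv} and
#' \code{Q.tsv}.
#'
#' @param fit a \code{cosine_fit}.
#' @param dir checkpoint directory (created if needed).
#' @return \code{dir} (for \code{save_model}) or a \code{cosine_fit}
#'   (for \code{load_model}).
#' @export
save_model <- function(fit, dir) {
  stopifnot(inherits(fit, "cosine_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  F <- fit$model$F; G <- fit$model$G
  rownames(F) <- fit$target_ids; colnames(F) <- paste0("k", seq_len(ncol(F)))
  rownames(G) <- fit$chemical_ids; colnames(G) <- paste0("k", seq_len(ncol(G)))
  write_table_matrix(F, file.path(dir, "F.tsv"))
  write_table_matrix(G, file.path(dir, "G.tsv"))
  W <- fit$W; dimnames(W) <- list(fit$target_ids, fit$chemical_ids)
  Q <- fit$Q; dimnames(Q) <- list(fit$target_ids, fit$chemical_ids)
  write_table_matrix(W, file.path(dir, "W.tsv"))
  write_table_matrix(Q, file.path(dir, "Q.tsv"))
  write_config(fit$model$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  config <- read_config(file.path(dir, "config.yaml"))
  F <- read_table_matrix(file.path(dir, "F.tsv"))
  G <- read_table_matrix(file.path(dir, "G.tsv"))
  W <- read_table_matrix(file.path(dir, "W.tsv"))
  Q <- read_table_matrix(file.path(dir, "Q.tsv"))
  model <- new_factor_model(F, G, config)
  finish_fit(structure(list(R = W,
                            target_ids = rownames(F),
                            chemical_ids = rownames(G)),
                       class = "interaction_dataset"),
             model, W, Q, numeric(0), NULL, model, NULL)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run a complete benchmark protocol with reproducibility metadata
#'
#' Orchestrates simulate/load, fit, cold-start predict and evaluate for one
#' of the supported protocols, writes the per-fold table as TSV and a JSON
#' manifest (resolved configuration, seeds, input checksums, package
#' version, per-stage timings), and returns the report. Identical manifests
#' imply identical metric outputs: every random choice is seeded.
#'
#' @param protocol one of \code{"cv5"} (5-fold chemical-wise CV),
#'   \code{"cv10x5"} (5 rounds of 10-fold CV), \code{"loocv_top1"},
#'   \code{"coldstart_tpr"}.
#' @param inputs either a synthetic fixture list (from
#'   \code{\link{simulate_screen}} / \code{\link{make_coldstart_fixture}})
#'   or a list with paths \code{interactions}, \code{target_sim},
#'   \code{chem_sim}.
#' @param config a \code{\link{cosine_config}}.
#' @param out_dir output directory; created if needed. \code{NULL} skips
#'   writing.
#' @param seed integer seed for fold assignment / stratification.
#' @param J,v cold-start parameters.
#' @param r_percents cutoff percentages for the cold-start recovery
#'   protocol.
#' @param quiet suppress stage messages.
#' @return The \code{eval_report}, with the manifest attached as
#'   \code{$manifest}.
#' @export
run_benchmark <- function(protocol = c("cv5", "cv10x5", "loocv_top1",
                                       "coldstart_tpr"),
                          inputs, config = cosine_config(),
                          out_dir = NULL, seed = 1L,
                          J = 5, v = 0.5, r_percents = c(1, 5, 10),
                          quiet = FALSE) {
  protocol <- match.arg(protocol)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  checksums <- list()
  if (!is.null(inputs$interactions) && is.character(inputs$interactions)) {
    stage_log(quiet, "[load] reading matrices")
    data <- read_interaction_matrix(inputs$interactions)
    al <- align_datasets(data,
                         read_similarity_matrix(inputs$target_sim),
                         read_similarity_matrix(inputs$chem_sim))
    checksums <- lapply(inputs[c("interactions", "target_sim", "chem_sim")],
                        function(p) unname(tools::md5sum(p)))
    fixture <- al
  } else {
    fixture <- inputs
  }
  timings["load"] <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  report <- switch(protocol,
    cv5 = run_chemical_cv(fixture$data, fixture$target_sim, fixture$chem_sim,
                          config, k = 5, rounds = 1, seed = seed,
                          J = J, v = v),
    cv10x5 = run_chemical_cv(fixture$data, fixture$target_sim,
                             fixture$chem_sim, config, k = 10, rounds = 5,
                             seed = seed, J = J, v = v),
    loocv_top1 = loocv_top1(fixture$data, fixture$target_sim,
                            fixture$chem_sim, config, J = J, v = v),
    coldstart_tpr = run_coldstart_tpr(fixture, config, seed = seed,
                                      J = J, v = v, r_percents = r_percents)
  )
  timings["evaluate"] <- proc.time()[["elapsed"]] - t1
  stage_log(quiet, "[evaluate] %s done in %.1fs", protocol,
            timings[["evaluate"]])

  manifest <- list(protocol = protocol,
                   config = unclass(config),
                   seed = seed, J = J, v = v,
                   input_checksums = checksums,
                   package_version = as.character(utils::packageVersion("cosine")),
                   timings_sec = as.list(round(timings, 3)))
  report$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$per_fold,
                       file.path(out_dir, paste0(protocol, "_per_fold.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # metrics file excludes timings so identical runs are byte-identical
    jsonlite::write_json(
      list(aggregate = as.list(report$aggregate), per_fold = report$per_fold),
      file.path(out_dir, paste0(protocol, "_metrics.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      manifest, file.path(out_dir, paste0(protocol, "_manifest.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  report
}

# cold-start recovery protocol: train without the designated chemicals'
# interactions, cold-start them, report TPR@r% per stratum
run_coldstart_tpr <- function(fixture, config, seed = 1L, J = 5, v = 0.5,
                              r_percents = c(1, 5, 10)) {
  stopifnot(!is.null(fixture$cold_info))
  strat <- coldstart_stratify(fixture$cold_info, seed = seed)
  test <- strat[strat$role == "test", , drop = FALSE]
  fit <- cosine_fit(fixture$train, fixture$target_sim, fixture$chem_sim,
                    config)
  fit <- apply_cold_start(fit, chem_sim = fixture$chem_sim,
                          new_chemicals = fixture$cold_chemicals,
                          J = J, v = v)
  P <- predict(fit)
  rows <- list()
  for (b in unique(test$lt_bin)) {
    members <- test[test$lt_bin == b, , drop = FALSE]
    for (r in r_percents) {
      tprs <- mapply(function(j, t_i) tpr_at_top_percent(P[, j], t_i, r),
                     members$chemical, members$hidden_target)
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = b, r_percent = r, n_chemicals = nrow(members),
                   tpr = mean(tprs))
    }
  }
  per <- do.call(rbind, rows)
  new_eval_report("coldstart_tpr", per,
                  c(tpr_mean = mean(per$tpr)),
                  list(seed = seed, J = J, v = v, config = config,
                       r_percents = r_percents))
}
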