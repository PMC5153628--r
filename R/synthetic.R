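#' Specification of a synthetic screening benchmark
#'
#' Describes a simulated protein-chemical screen with exactly the structure
#' the factorization model assumes: entities fall into a small number of
#' latent clusters (members of a cluster share interaction preferences), the
#' interaction matrix is low rank, and the similarity matrices reflect
#' distance in the same latent space (homophily holds by construction). The
#' \code{similarity_noise} knob perturbs the similarities to break homophily
#' controllably.
#'
#' @param m,n numbers of targets and chemicals.
#' @param rank true latent dimension.
#' @param n_target_clusters,n_chemical_clusters cluster counts.
#' @param interaction_density fraction of entries set to 1, in (0, 1).
#' @param similarity_noise sd of Gaussian perturbation added to the
#'   latent-derived similarities before clipping.
#' @param cluster_spread within-cluster sd of latent vectors around their
#'   centroid, relative to the unit centroid scale.
#' @param seed integer seed; the fixture is a deterministic function of the
#'   spec.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(m = 50, n = 80, rank = 3,
                           n_target_clusters = 4, n_chemical_clusters = 5,
                           interaction_density = 0.08,
                           similarity_noise = 0.05,
                           cluster_spread = 0.25,
                           seed = 1L) {
  stopifnot(m >= 1, n >= 1, rank >= 1, rank <= min(m, n),
            interaction_density > 0, interaction_density < 1,
            n_target_clusters >= 1, n_target_clusters <= m,
            n_chemical_clusters >= 1, n_chemical_clusters <= n,
            similarity_noise >= 0, cluster_spread >= 0)
  structure(list(m = as.integer(m), n = as.integer(n), rank = as.integer(rank),
                 n_target_clusters = as.integer(n_target_clusters),
                 n_chemical_clusters = as.integer(n_chemical_clusters),
                 interaction_density = interaction_density,
                 similarity_noise = similarity_noise,
                 cluster_spread = cluster_spread,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# latent vectors clustered around Gaussian centroids (unit scale);
# cluster labels cycle so every cluster is populated
clustered_latents <- function(k, rank, n_clusters, spread) {
  centroids <- matrix(stats::rnorm(n_clusters * rank, sd = 1), n_clusters, rank)
  labels <- rep_len(seq_len(n_clusters), k)
  centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(k * rank, sd = spread), k, rank)
}

# RBF similarity from latent geometry; bandwidth from the median squared
# distance so values spread over (0, 1]
latent_similarity <- function(L, noise_sd) {
  d2 <- as.matrix(stats::dist(L))^2
  h2 <- stats::median(d2[upper.tri(d2)])
  if (h2 <= 0) h2 <- 1
  S <- exp(-d2 / (2 * h2))
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S))
    S <- S + (E + t(E)) / 2  # symmetric perturbation
  }
  suppressWarnings(similarity_matrix(S))
}

#' Generate a synthetic screening fixture
#'
#' Draws clustered latent vectors for targets and chemicals, scores every
#' pair by the latent inner product, and marks the top
#' \code{interaction_density} fraction of entries as observed interactions
#' (deterministic quantile thresholding, so the positive count is exact).
#' Similarities are radial-basis-function kernels of latent distance, plus
#' optional noise, then symmetrized, clipped to [0, 1], unit diagonal — so
#' they are informative about interaction preferences exactly as the model
#' assumes.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param bernoulli logical; if TRUE, sample interactions as independent
#'   Bernoulli draws with logistic probabilities calibrated to the requested
#'   density instead of deterministic thresholding.
#' @return A list with \code{data} (\code{\link{interaction_dataset}}),
#'   \code{target_sim}, \code{chem_sim} (\code{\link{similarity_matrix}}),
#'   the ground-truth latent matrices \code{F_true}, \code{G_true}, the
#'   score matrix \code{score_true}, and the cluster label vectors.
#' @export
simulate_screen <- function(spec, bernoulli = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  A <- clustered_latents(spec$m, spec$rank, spec$n_target_clusters,
                         spec$cluster_spread)
  B <- clustered_latents(spec$n, spec$rank, spec$n_chemical_clusters,
                         spec$cluster_spread)
  X <- tcrossprod(A, B)
  n_pos <- round(spec$interaction_density * spec$m * spec$n)
  if (n_pos < 1 || n_pos >= spec$m * spec$n)
    stop("infeasible interaction density: ", spec$interaction_density)
  if (bernoulli) {
    # shift scores so the mean logistic probability matches the density
    shift <- stats::uniroot(function(s) mean(sigmoid(X + s)) -
                              spec$interaction_density,
                            interval = c(-50, 50))$root
    R <- matrix(stats::rbinom(length(X), 1, sigmoid(X + shift)), spec$m)
  } else {
    thr <- sort(X, decreasing = TRUE)[n_pos]
    R <- (X >= thr) * 1
  }
  dimnames(R) <- list(paste0("t", seq_len(spec$m)),
                      paste0("c", seq_len(spec$n)))
  M <- latent_similarity(A, spec$similarity_noise)
  N <- latent_similarity(B, spec$similarity_noise)
  M$ids <- rownames(R); dimnames(M$S) <- list(M$ids, M$ids)
  N$ids <- colnames(R); dimnames(N$S) <- list(N$ids, N$ids)
  list(data = interaction_dataset(R),
       target_sim = M, chem_sim = N,
       F_true = A, G_true = B, score_true = X,
       target_clusters = rep_len(seq_len(spec$n_target_clusters), spec$m),
       chemical_clusters = rep_len(seq_len(spec$n_chemical_clusters), spec$n),
       spec = spec)
}

#' Canonical benchmark fixtures
#'
#' Two fixture definitions used throughout the package's benchmarks.
#' \code{standard_benchmark_spec} is the workhorse recovery fixture: 50
#' targets by 80 chemicals, true rank 3, 8\% interaction density, mild
#' similarity noise. \code{coldstart_benchmark_spec} is larger and harder
#' (100 x 120, rank 4, 8 clusters per side, 5\% density, similarity noise
#' 0.15) so that top-10\%-of-ranks recovery for cold chemicals is not
#' saturated and the contribution of the weighted profile is measurable.
#'
#' @param seed integer seed.
#' @return A \code{\link{synthetic_spec}}.
#' @export
standard_benchmark_spec <- function(seed = 1L) {
  synthetic_spec(m = 50, n = 80, rank = 3,
                 n_target_clusters = 4, n_chemical_clusters = 5,
                 interaction_density = 0.08, similarity_noise = 0.05,
                 seed = seed)
}

#' @rdname standard_benchmark_spec
#' @export
coldstart_benchmark_spec <- function(seed = 1L) {
  synthetic_spec(m = 100, n = 120, rank = 4,
                 n_target_clusters = 8, n_chemical_clusters = 8,
                 interaction_density = 0.05, similarity_noise = 0.15,
                 seed = seed)
}

#' Hide a fraction of known interactions
#'
#' Flips \code{round(fraction * positives)} randomly chosen 1-entries to 0
#' and reports which, so recovery of the hidden interactions can be scored.
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param fraction fraction of positives to hide, in (0, 1).
#' @param seed integer seed for the sampling.
#' @return List with \code{data} (masked dataset) and \code{hidden}, a
#'   two-column matrix of (target, chemical) indices.
#' @export
hide_positives <- function(data, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  R <- int_mat(data)
  pos <- which(R == 1, arr.ind = TRUE)
  if (nrow(pos) < 1) stop("no positives to hide")
  n_hide <- round(fraction * nrow(pos))
  set.seed(seed)
  sel <- sample.int(nrow(pos), n_hide)
  hidden <- pos[sel, , drop = FALSE]
  R[hidden] <- 0
  list(data = interaction_dataset(R), hidden = hidden)
}

#' Corrupt an interaction matrix with noise
#'
#' Injects the two failure modes of real screening data: spurious recorded
#' interactions (\code{add_false_positives}: zeros flipped to ones) and
#' missing ones (\code{remove_true_positives}: ones flipped to zeros). The
#' flip count is \code{round(flip_fraction * current positives)} in both
#' modes, so the corruption level is expressed relative to the size of the
#' observed interaction set.
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param flip_fraction nonnegative fraction; 0 returns the data unchanged.
#' @param mode \code{"add_false_positives"} or \code{"remove_true_positives"}.
#' @param seed integer seed.
#' @return List with \code{data} (corrupted dataset) and \code{flipped}, a
#'   two-column index matrix of the altered cells.
#' @export
inject_noise <- function(data, flip_fraction,
                         mode = c("add_false_positives",
                                  "remove_true_positives"),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(flip_fraction >= 0)
  R <- int_mat(data)
  n_pos <- sum(R == 1)
  n_flip <- round(flip_fraction * n_pos)
  if (n_flip == 0)
    return(list(data = interaction_dataset(R),
                flipped = matrix(integer(0), 0, 2)))
  from <- if (mode == "add_false_positives") 0 else 1
  cells <- which(R == from, arr.ind = TRUE)
  if (n_flip > nrow(cells))
    stop("requested ", n_flip, " flips but only ", nrow(cells),
         " eligible entries")
  set.seed(seed)
  flipped <- cells[sample.int(nrow(cells), n_flip), , drop = FALSE]
  R[flipped] <- 1 - from
  list(data = interaction_dataset(R), flipped = flipped)
}

#' Build a cold-start fixture with single hidden targets
#'
#' Emulates the cold-start evaluation setting: a designated subset of
#' chemicals each has exactly one known target, and that single interaction
#' is hidden from training, so the designated chemicals enter the fit with
#' all-zero columns. Per-chemical stratification metadata is attached: the
#' number of ligands its (hidden) target has among training chemicals, and
#' its maximum similarity to any non-designated chemical.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param n_cold number of designated cold-start chemicals (must not exceed
#'   the number of chemicals with at least one interaction).
#' @return List with \code{train} (dataset whose designated columns are all
#'   zero), \code{full} (dataset in which each designated chemical has
#'   exactly its one true target), \code{target_sim}, \code{chem_sim},
#'   \code{cold_chemicals} (indices), and \code{cold_info}, a data.frame
#'   with columns \code{chemical}, \code{hidden_target},
#'   \code{ligands_per_target}, \code{max_chem_similarity}.
#' @export
make_coldstart_fixture <- function(spec, n_cold = 16) {
  fx <- simulate_screen(spec)
  R <- fx$data$R
  with_pos <- which(colSums(R) >= 1)
  if (length(with_pos) < n_cold)
    stop("only ", length(with_pos), " chemicals have interactions; ",
         "cannot designate ", n_cold, " cold-start chemicals")
  set.seed(spec$seed + 1L)
  cold <- sort(sample(with_pos, n_cold))
  R_full <- R
  for (j in cold) {
    # the single true target: the chemical's strongest known interaction
    pos_i <- which(R[, j] == 1)
    keep <- pos_i[which.max(fx$score_true[pos_i, j])]
    R_full[, j] <- 0
    R_full[keep, j] <- 1
  }
  R_train <- R_full
  R_train[, cold] <- 0
  hidden_target <- vapply(cold, function(j) which(R_full[, j] == 1)[1], 1L)
  lig <- rowSums(R_train)  # ligands per target among training chemicals
  n_sim <- fx$chem_sim$S
  max_sim <- vapply(cold, function(j) max(n_sim[j, -cold]), 1.0)
  list(train = interaction_dataset(R_train),
       full = interaction_dataset(R_full),
       target_sim = fx$target_sim, chem_sim = fx$chem_sim,
       cold_chemicals = cold,
       cold_info = data.frame(chemical = cold,
                              hidden_target = hidden_target,
                              ligands_per_target = lig[hidden_target],
                              max_chem_similarity = max_sim),
       truth = fx)
}
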