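test_that("AUC matches its definition and the pairwise oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(14)
  for (i in 1:20) {
    scores <- round(runif(20), 1)  # rounding forces ties
    labels <- rbinom(20, 1, 0.4)
    if (sum(labels) %in% c(0, 20)) next
    expect_equal(auc_score(scores, labels), pairwise_auc(scores, labels))
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "undefined")
})

test_that("AUPR matches closed forms and the threshold-sweep oracle", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # a single positive at rank k of n scores 1/k
  for (k in c(1, 3, 7)) {
    scores <- seq(1, 0.1, length.out = 10)
    labels <- rep(0, 10); labels[k] <- 1
    expect_equal(aupr_score(scores, labels), 1 / k)
  }
  set.seed(15)
  for (i in 1:20) {
    scores <- round(runif(25), 1)
    labels <- rbinom(25, 1, 0.3)
    if (sum(labels) == 0) next
    expect_equal(aupr_score(scores, labels), sweep_aupr(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(aupr_score(1:3, c(0, 0, 0)), "undefined")
})

test_that("chemical folds partition evenly and reproducibly", {
  folds <- chemical_cv_split(10, k = 5, seed = 1)[[1]]
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), 1:10)

  # uneven split: sizes differ by at most one
  folds2 <- chemical_cv_split(23, k = 5, seed = 2)[[1]]
  expect_lte(diff(range(lengths(folds2))), 1)
  expect_setequal(unlist(folds2), 1:23)

  # every round is a fresh partition
  rounds <- chemical_cv_split(12, k = 3, rounds = 4, seed = 3)
  for (rd in rounds) expect_setequal(unlist(rd), 1:12)

  expect_identical(chemical_cv_split(30, 5, 2, seed = 7),
                   chemical_cv_split(30, 5, 2, seed = 7))
  expect_false(identical(chemical_cv_split(30, 5, 1, seed = 7),
                         chemical_cv_split(30, 5, 1, seed = 8)))
  expect_error(chemical_cv_split(4, k = 5), "k <= n_chemicals")
})

test_that("TPR at top r% uses the rounded cutoff rank and worst-rank ties", {
  # 3500 targets at r = 1: cutoff rank 35
  scores <- seq(3500, 1) / 3500
  expect_equal(tpr_at_top_percent(scores, 35, 1), 1)   # rank 35: in
  expect_equal(tpr_at_top_percent(scores, 36, 1), 0)   # rank 36: out
  # a top-ranked true target always counts
  expect_equal(tpr_at_top_percent(c(5, 1, 2, 3), 1, 10), 1)
  # tie at the cutoff resolves pessimistically
  expect_equal(tpr_at_top_percent(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 1, 10), 0)
  # monotone in r
  set.seed(16)
  sc <- runif(200); tt <- sample(200, 12)
  tprs <- vapply(c(1, 2, 5, 10, 25, 50, 100),
                 function(r) tpr_at_top_percent(sc, tt, r), 1.0)
  expect_true(all(diff(tprs) >= 0))
})

test_that("TPR of random predictions is calibrated to r percent", {
  set.seed(18)
  vals <- replicate(1000, tpr_at_top_percent(runif(100), sample(100, 10), 10))
  expect_lt(abs(mean(vals) - 0.10), 0.01)
})

test_that("AUC is centered under label permutation", {
  set.seed(19)
  scores <- runif(50)
  labels <- rep(c(1, 0), c(15, 35))
  aucs <- replicate(200, auc_score(scores, sample(labels)))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("paired fold test matches the textbook statistic", {
  a <- c(0.90, 0.85, 0.88, 0.92, 0.87)
  b <- a - c(0.020, 0.010, 0.030, 0.015, 0.025)
  res <- fold_significance(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_true(res$significant)

  same <- fold_significance(a, a)
  expect_true(same$degenerate)
  expect_false(same$significant)

  far <- fold_significance(a + c(10.0, 10.1, 9.9, 10.05, 9.95), a)
  expect_lt(far$p_value, 1e-6)
})

test_that("cold-start strata bins and halving behave as designed", {
  info <- data.frame(chemical = 1:9,
                     hidden_target = rep(1:3, 3),
                     ligands_per_target = c(7, 1, 5, 12, 16, 21, 3, 9, 18),
                     max_chem_similarity = c(0.05, 0.55, 0.99, 0.3, 0.41,
                                             0.7, 0.12, 0.65, 0.88))
  out <- coldstart_stratify(info, seed = 4)
  expect_equal(out$lt_bin[1], "6-10")
  expect_equal(out$mcs_bin[1], "[0.0,0.1)")
  expect_equal(out$lt_bin, c("6-10", "1-5", "1-5", "11-15", "16-20",
                             ">20", "1-5", "6-10", "16-20"))
  # similarity 0.99 lands in the top closed bin
  expect_equal(out$mcs_bin[3], "[0.9,1.0)")
  # every chemical gets exactly one bin of each kind and a role
  expect_false(anyNA(out$lt_bin))
  expect_false(anyNA(out$mcs_bin))
  expect_true(all(out$role %in% c("test", "train")))
  # halving within each ligand bin
  for (b in unique(out$lt_bin)) {
    nb <- sum(out$lt_bin == b)
    expect_equal(sum(out$lt_bin == b & out$role == "test"), ceiling(nb / 2))
  }
})

test_that("leave-one-out Top-1 counts exhaustive and twin chemicals correctly", {
  # one chemical interacts with every target: always a correct Top-1
  set.seed(23)
  R <- matrix(rbinom(30, 1, 0.3), 5, 6)
  R[, 1] <- 1
  ds <- interaction_dataset(R)
  M <- random_similarity(5); N <- random_similarity(6)
  rep1 <- loocv_top1(ds, M, N,
                     cosine_config(rank = 2, iterations = 40, seed = 23),
                     retrain = "fast")
  expect_true(rep1$per_fold$top1_correct[rep1$per_fold$chemical == 1])

  # twin chemicals with identical targets and similarity 1: perfect Top-1
  pairs <- matrix(rbinom(24, 1, 0.35), 6, 4)
  pairs[colSums(pairs) == 0] <- 1
  R2 <- pairs[, rep(1:4, each = 2)]
  colnames(R2) <- paste0("c", 1:8); rownames(R2) <- paste0("t", 1:6)
  N2 <- diag(8) * 0 + 0.1
  for (p in 1:4) {
    i <- 2 * p - 1
    N2[i, i + 1] <- N2[i + 1, i] <- 1
  }
  diag(N2) <- 1
  rep2 <- loocv_top1(interaction_dataset(R2), random_similarity(6), N2,
                     cosine_config(rank = 3, iterations = 150, seed = 24),
                     J = 1, v = 0, retrain = "full")
  expect_equal(unname(rep2$aggregate["top1_percent"]), 100)
})
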