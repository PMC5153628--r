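# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use scalar loops and from-scratch
# formulas, never the package's own linear-algebra paths.

# scalar-loop evaluation of the full training loss
loop_loss <- function(F, G, R, W, Q, M, N,
                      mode = "logistic",
                      lambda_f = 0, lambda_g = 0,
                      lambda_m = 0, lambda_n = 0) {
  m <- nrow(F); n <- nrow(G)
  data_term <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    x <- sum(F[i, ] * G[j, ])
    t_eff <- R[i, j] + Q[i, j]
    data_term <- data_term + if (mode == "logistic") {
      W[i, j] * (log(1 + exp(x)) - t_eff * x)
    } else {
      W[i, j] * (t_eff - x)^2
    }
  }
  hom <- function(L, S) {
    acc <- 0
    for (i in seq_len(nrow(L))) for (j in seq_len(nrow(L)))
      acc <- acc + S[i, j] * sum((L[i, ] - L[j, ])^2)
    acc / 2
  }
  data_term +
    lambda_f / 2 * sum(F^2) + lambda_g / 2 * sum(G^2) +
    lambda_m / 2 * hom(F, M) + lambda_n / 2 * hom(G, N)
}

# pairwise-sum homophily oracle
loop_homophily <- function(L, S) {
  acc <- 0
  for (i in seq_len(nrow(L))) for (j in seq_len(nrow(L)))
    acc <- acc + S[i, j] * sum((L[i, ] - L[j, ])^2)
  acc / 2
}

# O(n^2) pairwise-comparison AUC, ties counted 1/2
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# threshold-sweep AUPR, recomputing precision/recall from scratch at every
# distinct score
sweep_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thresholds) {
    called <- scores >= t
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# central finite differences of the loss with respect to one factor matrix
fd_gradient <- function(model, R, W, Q, M, N, which = "F", h = 1e-6) {
  L <- model[[which]]
  out <- L * 0
  for (i in seq_along(L)) {
    mp <- model; mm <- model
    mp[[which]][i] <- mp[[which]][i] + h
    mm[[which]][i] <- mm[[which]][i] - h
    out[i] <- (cosine_loss(mp, R, W, Q, M, N) -
                 cosine_loss(mm, R, W, Q, M, N)) / (2 * h)
  }
  out
}

# a random small training instance with valid shapes
random_instance <- function(m, n, r, seed, mode = "logistic",
                            lambdas = c(0.2, 0.3, 0.15, 0.25)) {
  set.seed(seed)
  cfg <- cosine_config(rank = r, mode = mode,
                       lambda_f = lambdas[1], lambda_g = lambdas[2],
                       lambda_m = lambdas[3], lambda_n = lambdas[4])
  F <- matrix(rnorm(m * r), m, r)
  G <- matrix(rnorm(n * r), n, r)
  R <- matrix(rbinom(m * n, 1, 0.3), m, n)
  W <- initial_weights(R)
  Q <- matrix(runif(m * n) * 0.3, m, n) * (R == 0)
  M <- random_similarity(m)
  N <- random_similarity(n)
  list(model = cosine:::new_factor_model(F, G, cfg),
       R = R, W = W, Q = Q, M = M, N = N, cfg = cfg)
}

random_similarity <- function(k) {
  S <- matrix(runif(k * k), k, k)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# evaluate TPR@r% of the hidden single targets of a cold-start fixture
coldstart_tpr10 <- function(P, cold_info, r = 10) {
  mean(mapply(function(j, t_i) tpr_at_top_percent(P[, j], t_i, r),
              cold_info$chemical, cold_info$hidden_target))
}
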