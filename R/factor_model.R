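#' Model and training configuration
#'
#' Collects every tunable of the factorization in one place. The latent rank
#' \code{rank} caps the number of interaction patterns the model can express;
#' \code{lambda_f}/\code{lambda_g} are Gaussian-prior (Frobenius) penalties on
#' the target and chemical factors; \code{lambda_m}/\code{lambda_n} scale the
#' graph-Laplacian homophily penalties built from the protein and chemical
#' similarity matrices. The two-pass scheme is controlled by the weight
#' thresholds \code{p_low}/\code{p_high}: after pass one, entries whose
#' predicted probability falls below \code{p_low} or at/above \code{p_high}
#' gain one unit of weight, and entries at/above \code{p_high} are imputed
#' to 1 (others to \code{max(r, p)}).
#'
#' @param rank number of latent factors (r << min(m, n)).
#' @param lambda_f,lambda_g nonnegative Frobenius penalties on F and G.
#' @param lambda_m,lambda_n nonnegative homophily penalties.
#' @param mode \code{"logistic"} (default; probabilities via the logistic
#'   link) or \code{"linear"} (weighted squared error).
#' @param learning_rate AdaGrad master step size.
#' @param adagrad_epsilon numerical floor in the AdaGrad denominator.
#' @param iterations full-batch gradient iterations per pass.
#' @param init_scale sd of the Gaussian initialization of F and G; default
#'   \code{1/sqrt(rank)} keeps initial scores O(1).
#' @param p_low,p_high confidence thresholds for reweighting/imputation,
#'   0 < p_low < p_high < 1.
#' @param two_pass logical; run the reweight-impute second pass (default).
#' @param seed integer seed for the factor initialization.
#' @return A list of class \code{cosine_config}.
#' @export
cosine_config <- function(rank = 5,
                          lambda_f = 0.2, lambda_g = 0.2,
                          lambda_m = 0.2, lambda_n = 0.2,
                          mode = c("logistic", "linear"),
                          learning_rate = 0.7,
                          adagrad_epsilon = 1e-8,
                          iterations = 600,
                          init_scale = NULL,
                          p_low = 0.1, p_high = 0.9,
                          two_pass = TRUE,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(init_scale)) init_scale <- 1 / sqrt(rank)
  stopifnot(rank >= 1, iterations >= 1, learning_rate >= 0,
            adagrad_epsilon > 0, init_scale > 0,
            lambda_f >= 0, lambda_g >= 0, lambda_m >= 0, lambda_n >= 0)
  if (!(p_low > 0 && p_low < p_high && p_high < 1))
    stop("thresholds must satisfy 0 < p_low < p_high < 1")
  structure(list(rank = as.integer(rank),
                 lambda_f = lambda_f, lambda_g = lambda_g,
                 lambda_m = lambda_m, lambda_n = lambda_n,
                 mode = mode,
                 learning_rate = learning_rate,
                 adagrad_epsilon = adagrad_epsilon,
                 iterations = as.integer(iterations),
                 init_scale = init_scale,
                 p_low = p_low, p_high = p_high,
                 two_pass = isTRUE(two_pass),
                 seed = as.integer(seed)),
            class = "cosine_config")
}

#' Overflow-safe logistic function
#'
#' @param x numeric vector or matrix of scores.
#' @return \code{1 / (1 + exp(-x))}, evaluated without overflow for large
#'   \code{|x|}; values are strictly inside (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  # keep probabilities strictly inside (0, 1) even at saturating scores
  pmin(pmax(out, 1e-300), 1 - 2^-53)
}

# log(1 + exp(x)) without overflow: x + log1p(exp(-x)) for x > 0
softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

new_factor_model <- function(F, G, config) {
  stopifnot(ncol(F) == ncol(G))
  structure(list(F = F, G = G, config = config), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d targets x %d chemicals, rank %d, %s link\n",
              nrow(x$F), nrow(x$G), ncol(x$F), x$config$mode))
  invisible(x)
}

#' Predicted interaction probabilities
#'
#' For the logistic link, entry (i, j) is \code{sigmoid(f_i . g_j)}, the
#' modeled probability that target i interacts with chemical j; for the
#' linear mode the raw scores \code{F \%*\% t(G)} are returned.
#'
#' @param model a \code{factor_model} (from \code{\link{cosine_fit}}).
#' @return An m x n numeric matrix carrying the model's identifiers when the
#'   factors do.
#' @export
predict_interactions <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  if (any(!is.finite(model$F)) || any(!is.finite(model$G)))
    stop("non-finite latent factors")
  X <- tcrossprod(model$F, model$G)
  if (model$config$mode == "logistic") sigmoid(X) else X
}

#' @export
predict.factor_model <- function(object, ...) predict_interactions(object)

#' Graph-Laplacian homophily penalty
#'
#' Half the similarity-weighted sum of squared distances between latent
#' rows: \code{0.5 * sum_ij S[i,j] * ||L[i,] - L[j,]||^2}, evaluated as the
#' quadratic form \code{trace(t(L) \%*\% (D - S) \%*\% L)} with
#' \code{D = diag(rowSums(S))}. Minimizing it pulls the latent vectors of
#' similar entities together (homophily).
#'
#' @param L k x r latent matrix.
#' @param S k x k symmetric similarity matrix (plain matrix or
#'   \code{\link{similarity_matrix}}).
#' @return Nonnegative scalar.
#' @export
homophily_penalty <- function(L, S) {
  S <- sim_mat(S)
  stopifnot(nrow(S) == nrow(L))
  if (max(abs(S - t(S))) > 1e-9)
    stop("similarity matrix must be symmetric; validate with similarity_matrix()")
  LapL <- rowSums(S) * L - S %*% L
  sum(LapL * L)
}

sim_mat <- function(S) if (inherits(S, "similarity_matrix")) S$S else as.matrix(S)
int_mat <- function(R) if (inherits(R, "interaction_dataset")) R$R else as.matrix(R)

# shared shape checks for loss/gradient evaluation
check_shapes <- function(F, G, R, W, Q, M, N) {
  m <- nrow(F); n <- nrow(G)
  if (!all(dim(R) == c(m, n))) stop("interaction matrix shape mismatch")
  if (!all(dim(W) == c(m, n))) stop("weight matrix shape mismatch")
  if (!all(dim(Q) == c(m, n))) stop("impute matrix shape mismatch")
  if (!all(dim(M) == c(m, m))) stop("target similarity shape mismatch")
  if (!all(dim(N) == c(n, n))) stop("chemical similarity shape mismatch")
  invisible(TRUE)
}

#' Training loss of the dual-regularized weighted factorization
#'
#' The objective minimized during training. With scores
#' \code{X = F t(G)} and effective targets \code{T = R + Q}, the logistic
#' data term is \code{sum(W * (softplus(X) - T * X))} — the weighted negative
#' log-likelihood of the logistic link — and the linear data term is
#' \code{sum(W * (T - X)^2)}. Both are augmented by
#' \code{lambda_f/2 ||F||^2 + lambda_g/2 ||G||^2} and by
#' \code{lambda_m/2} and \code{lambda_n/2} times the target and chemical
#' \code{\link{homophily_penalty}} terms.
#'
#' @param model a \code{factor_model}.
#' @param R binary interaction matrix (or \code{interaction_dataset}).
#' @param W positive weight matrix.
#' @param Q impute matrix; \code{R + Q} must lie in [0, 1].
#' @param M,N target and chemical similarity matrices.
#' @param parts logical; return the named additive components instead of
#'   their sum.
#' @return Scalar loss, or a named numeric vector when \code{parts = TRUE}.
#' @export
cosine_loss <- function(model, R, W, Q, M, N, parts = FALSE) {
  R <- int_mat(R); M <- sim_mat(M); N <- sim_mat(N)
  F <- model$F; G <- model$G; cfg <- model$config
  check_shapes(F, G, R, W, Q, M, N)
  X <- tcrossprod(F, G)
  T_eff <- R + Q
  data_term <- if (cfg$mode == "logistic") {
    sum(W * (softplus(X) - T_eff * X))
  } else {
    sum(W * (T_eff - X)^2)
  }
  comp <- c(data = data_term,
            ridge_f = cfg$lambda_f / 2 * sum(F * F),
            ridge_g = cfg$lambda_g / 2 * sum(G * G),
            homophily_m = cfg$lambda_m / 2 * homophily_penalty(F, M),
            homophily_n = cfg$lambda_n / 2 * homophily_penalty(G, N))
  if (parts) comp else sum(comp)
}

#' Analytic gradients of the training loss
#'
#' For the logistic mode the data-term residual is \code{W * (P - (R + Q))}
#' with \code{P = sigmoid(F t(G))}; for the linear mode it is
#' \code{2 * W * (X - (R + Q))}. The gradient with respect to F is
#' \code{residual \%*\% G + lambda_f * F + lambda_m * (D_M - M) \%*\% F}
#' and symmetrically for G.
#'
#' @inheritParams cosine_loss
#' @return List with matrices \code{dF} (m x r) and \code{dG} (n x r).
#' @export
cosine_gradients <- function(model, R, W, Q, M, N) {
  R <- int_mat(R); M <- sim_mat(M); N <- sim_mat(N)
  F <- model$F; G <- model$G; cfg <- model$config
  check_shapes(F, G, R, W, Q, M, N)
  X <- tcrossprod(F, G)
  T_eff <- R + Q
  resid <- if (cfg$mode == "logistic") {
    W * (sigmoid(X) - T_eff)
  } else {
    2 * W * (X - T_eff)
  }
  dF <- resid %*% G + cfg$lambda_f * F +
    cfg$lambda_m * (rowSums(M) * F - M %*% F)
  dG <- crossprod(resid, F) + cfg$lambda_g * G +
    cfg$lambda_n * (rowSums(N) * G - N %*% G)
  list(dF = dF, dG = dG)
}
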