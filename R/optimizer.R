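#' Minimize the training loss with AdaGrad
#'
#' Full-batch gradient descent with per-coordinate AdaGrad step sizes:
#' each coordinate moves by
#' \code{-learning_rate * g / (sqrt(sum of past g^2) + epsilon)}.
#' Full-batch updates keep runs deterministic for a fixed initialization.
#'
#' @param model a \code{factor_model} holding the initialized factors and
#'   configuration.
#' @param R,W,Q,M,N training matrices as in \code{\link{cosine_loss}}.
#' @param iterations optional override of \code{model$config$iterations}.
#' @return List with the optimized \code{model} and the numeric
#'   \code{loss_trace} (loss after each iteration, length \code{iterations}).
#' @export
adagrad_minimize <- function(model, R, W, Q, M, N, iterations = NULL) {
  cfg <- model$config
  if (is.null(iterations)) iterations <- cfg$iterations
  R <- int_mat(R); M <- sim_mat(M); N <- sim_mat(N)
  F <- model$F; G <- model$G
  accF <- matrix(0, nrow(F), ncol(F))
  accG <- matrix(0, nrow(G), ncol(G))
  eta <- cfg$learning_rate; eps <- cfg$adagrad_epsilon
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    gr <- cosine_gradients(model, R, W, Q, M, N)
    accF <- accF + gr$dF^2
    accG <- accG + gr$dG^2
    F <- F - eta * gr$dF / (sqrt(accF) + eps)
    G <- G - eta * gr$dG / (sqrt(accG) + eps)
    model$F <- F; model$G <- G
    trace[it] <- cosine_loss(model, R, W, Q, M, N)
    if (!is.finite(trace[it]))
      stop("non-finite loss at iteration ", it,
           "; reduce the learning rate or regularize more strongly")
  }
  list(model = model, loss_trace = trace)
}

init_factors <- function(m, n, cfg) {
  set.seed(cfg$seed)
  F <- matrix(stats::rnorm(m * cfg$rank, sd = cfg$init_scale), m, cfg$rank)
  G <- matrix(stats::rnorm(n * cfg$rank, sd = cfg$init_scale), n, cfg$rank)
  list(F = F, G = G)
}

#' Fit the two-pass dual-regularized factorization
#'
#' Pass one minimizes the loss with imputation values Q = 0 and the initial
#' position-specific weights (6 on known interactions, 1 elsewhere). The
#' pass-one probabilities then drive the reweighting (+1 on confidently
#' predicted entries) and the imputation rule (effective target 1 at or
#' above \code{p_high}, otherwise \code{max(r, p)}), and pass two
#' re-minimizes with the updated weights and targets, warm-starting from the
#' pass-one factors with fresh AdaGrad accumulators.
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param target_sim,chem_sim \code{\link{similarity_matrix}} objects (or
#'   plain symmetric matrices) for targets and chemicals.
#' @param config a \code{\link{cosine_config}}.
#' @param Q_override optional user-supplied impute matrix applied in pass
#'   two in place of the probability-driven rule (external evidence hook);
#'   \code{R + Q_override} must lie in [0, 1].
#' @return An object of class \code{cosine_fit}: the pass-two
#'   \code{factor_model} in \code{$model} plus the training state
#'   (\code{W}, \code{Q}, both loss traces, the pass-one model and
#'   probabilities) and the identifier vectors.
#' @examples
#' fx <- simulate_screen(synthetic_spec(m = 20, n = 30, seed = 7))
#' fit <- cosine_fit(fx$data, fx$target_sim, fx$chem_sim,
#'                   cosine_config(rank = 3, iterations = 50, seed = 7))
#' P <- predict(fit)
#' @export
cosine_fit <- function(data, target_sim, chem_sim,
                       config = cosine_config(), Q_override = NULL) {
  stopifnot(inherits(config, "cosine_config"))
  R <- int_mat(data)
  M <- sim_mat(target_sim); N <- sim_mat(chem_sim)
  m <- nrow(R); n <- ncol(R)
  if (config$rank > min(m, n))
    stop("rank must not exceed min(targets, chemicals)")
  fg <- init_factors(m, n, config)
  model <- new_factor_model(fg$F, fg$G, config)

  W1 <- initial_weights(R)
  Q1 <- matrix(0, m, n)
  pass1 <- adagrad_minimize(model, R, W1, Q1, M, N)
  P1 <- sigmoid(tcrossprod(pass1$model$F, pass1$model$G))

  if (!config$two_pass) {
    return(finish_fit(data, pass1$model, W1, Q1, pass1$loss_trace, NULL,
                      pass1$model, P1))
  }
  W2 <- update_weights(W1, P1, config$p_low, config$p_high)
  Q2 <- if (is.null(Q_override)) {
    impute_values(R, P1, config$p_high)
  } else {
    stopifnot(all(dim(Q_override) == c(m, n)),
              all(R + Q_override >= 0), all(R + Q_override <= 1))
    Q_override
  }
  pass2 <- adagrad_minimize(pass1$model, R, W2, Q2, M, N)
  finish_fit(data, pass2$model, W2, Q2, pass1$loss_trace, pass2$loss_trace,
             pass1$model, P1)
}

finish_fit <- function(data, model, W, Q, trace1, trace2, model1, P1) {
  ids <- if (inherits(data, "interaction_dataset")) {
    list(target_ids = data$target_ids, chemical_ids = data$chemical_ids)
  } else {
    list(target_ids = rownames(data), chemical_ids = colnames(data))
  }
  rownames(model$F) <- ids$target_ids
  rownames(model$G) <- ids$chemical_ids
  structure(list(model = model,
                 W = W, Q = Q,
                 loss_trace_pass1 = trace1,
                 loss_trace_pass2 = trace2,
                 model_pass1 = model1,
                 prob_pass1 = P1,
                 target_ids = ids$target_ids,
                 chemical_ids = ids$chemical_ids),
            class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine_fit: %d targets x %d chemicals, rank %d, %s link\n",
              nrow(x$model$F), nrow(x$model$G), ncol(x$model$F),
              x$model$config$mode))
  cat(sprintf("  pass-1 final loss %.4f", tail_val(x$loss_trace_pass1)))
  if (!is.null(x$loss_trace_pass2))
    cat(sprintf(", pass-2 final loss %.4f", tail_val(x$loss_trace_pass2)))
  cat("\n")
  invisible(x)
}

tail_val <- function(x) x[length(x)]

#' @export
predict.cosine_fit <- function(object, ...) {
  P <- predict_interactions(object$model)
  dimnames(P) <- list(object$target_ids, object$chemical_ids)
  P
}
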