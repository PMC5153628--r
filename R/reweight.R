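#' Position-specific confidence weights for the first pass
#'
#' Known interactions carry substantially more evidence than the ambiguous
#' zeros of one-class data, so they get weight 6 while every other entry gets
#' the baseline weight 1.
#'
#' @param data an \code{\link{interaction_dataset}} or a 0/1 matrix.
#' @return Matrix of the same shape with entries in \{1, 6\}.
#' @export
initial_weights <- function(data) {
  R <- int_mat(data)
  ifelse(R == 1, 6, 1)
}

#' Increment weights on confidently predicted entries
#'
#' After the first pass, entries whose predicted probability is extreme in
#' either direction (\code{p < p_low} or \code{p >= p_high}) are considered
#' confidently classified and their weight is increased by one for the
#' second pass. The lower branch is open and the upper closed, matching the
#' imputation boundary.
#'
#' @param W current weight matrix.
#' @param P matrix of pass-one interaction probabilities.
#' @param p_low,p_high thresholds with 0 < p_low < p_high < 1.
#' @return Updated weight matrix; never smaller than \code{W} entrywise.
#' @export
update_weights <- function(W, P, p_low = 0.1, p_high = 0.9) {
  if (!(p_low > 0 && p_low < p_high && p_high < 1))
    stop("thresholds must satisfy 0 < p_low < p_high < 1")
  stopifnot(all(dim(W) == dim(P)))
  W + (P < p_low | P >= p_high)
}

#' Imputation values from first-pass probabilities
#'
#' Builds the effective training target for the second pass. An entry
#' predicted at or above \code{p_high} is imputed to a full 1; otherwise the
#' effective target is \code{max(r, p)}, so verified interactions (r = 1)
#' are never watered down and plausible-but-uncertain entries enter as soft
#' positives. The returned matrix is \code{Q = T - R}, the adjustment to add
#' to the observed matrix.
#'
#' @param data an \code{\link{interaction_dataset}} or 0/1 matrix.
#' @param P matrix of pass-one interaction probabilities.
#' @param p_high impute threshold in (0, 1).
#' @return Matrix Q with \code{0 <= R + Q <= 1} and \code{Q == 0} wherever
#'   \code{R == 1}.
#' @export
impute_values <- function(data, P, p_high = 0.9) {
  R <- int_mat(data)
  stopifnot(all(dim(R) == dim(P)), p_high > 0, p_high < 1)
  T_eff <- ifelse(P >= p_high, 1, pmax(R, P))
  T_eff - R
}
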