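#' Weighted-profile latent vector for one entity
#'
#' The cold-start rule: blend an entity's trained latent vector with the
#' similarity-weighted mean of its nearest neighbors' vectors,
#' \code{v * trained + (1 - v) * sum(s_j * f_j) / sum(s_j)}. With
#' \code{v = 1} the trained row is returned unchanged; with \code{v = 0} the
#' profile is the pure neighbor mean. Neighbors with zero similarity carry
#' no information and are excluded; when no neighbor has positive
#' similarity, the trained row is returned with a warning.
#'
#' @param trained_row length-r latent vector from the factorization.
#' @param neighbor_rows J x r matrix of neighbor latent vectors.
#' @param neighbor_sims length-J vector of nonnegative similarities.
#' @param v blend weight in [0, 1] on the trained row.
#' @return Length-r numeric vector.
#' @export
weighted_profile_row <- function(trained_row, neighbor_rows, neighbor_sims,
                                 v = 0.5) {
  stopifnot(v >= 0, v <= 1, length(neighbor_sims) == nrow(neighbor_rows),
            all(neighbor_sims >= 0))
  keep <- neighbor_sims > 0
  s_total <- sum(neighbor_sims[keep])
  if (s_total <= 0) {
    warning("no neighbor with positive similarity; returning trained row")
    return(trained_row)
  }
  profile <- colSums(neighbor_rows[keep, , drop = FALSE] *
                       neighbor_sims[keep]) / s_total
  v * trained_row + (1 - v) * profile
}

# top-J neighbors by similarity among the candidate pool;
# ties broken by pool index order for determinism
top_neighbors <- function(sims, pool, J) {
  ord <- pool[order(-sims[pool], pool)]
  ord[seq_len(min(J, length(ord)))]
}

#' Apply the weighted-profile cold start to a fitted model
#'
#' Replaces the latent rows of designated new targets and/or chemicals —
#' entities with no observed interactions — by their weighted profile
#' (\code{\link{weighted_profile_row}}). Neighbors are drawn only from
#' entities that are not themselves new (those with interaction data), and
#' the top \code{J} by similarity are used.
#'
#' @param fit a \code{cosine_fit} (or a bare \code{factor_model}).
#' @param target_sim,chem_sim similarity matrices aligned with the model.
#' @param new_targets,new_chemicals identifiers (or indices) of the
#'   entities to treat as cold; empty by default.
#' @param J number of nearest neighbors, at least 1.
#' @param v blend weight in [0, 1] on the trained latent row.
#' @return An object of the same class as \code{fit} with the designated
#'   rows of F and/or G replaced; all other rows untouched.
#' @export
apply_cold_start <- function(fit, target_sim = NULL, chem_sim = NULL,
                             new_targets = integer(0),
                             new_chemicals = integer(0),
                             J = 5, v = 0.5) {
  stopifnot(J >= 1)
  is_fit <- inherits(fit, "cosine_fit")
  model <- if (is_fit) fit$model else fit
  if (length(new_targets) > 0) {
    M <- sim_mat(target_sim)
    model$F <- cold_start_rows(model$F, M, resolve_idx(new_targets, rownames(model$F)), J, v)
  }
  if (length(new_chemicals) > 0) {
    N <- sim_mat(chem_sim)
    model$G <- cold_start_rows(model$G, N, resolve_idx(new_chemicals, rownames(model$G)), J, v)
  }
  if (is_fit) { fit$model <- model; fit } else model
}

resolve_idx <- function(ids, names_vec) {
  if (is.numeric(ids)) return(as.integer(ids))
  idx <- match(ids, names_vec)
  if (anyNA(idx))
    stop("unknown identifiers: ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

cold_start_rows <- function(L, S, new_idx, J, v) {
  stopifnot(nrow(S) == nrow(L))
  pool <- setdiff(seq_len(nrow(L)), new_idx)
  if (length(pool) == 0)
    stop("no entities with interaction data to serve as neighbors")
  L_trained <- L  # profiles are built from trained rows, not updated ones
  for (i in new_idx) {
    nb <- top_neighbors(S[i, ], pool, J)
    L[i, ] <- weighted_profile_row(L_trained[i, ],
                                   L_trained[nb, , drop = FALSE],
                                   S[i, nb], v)
  }
  L
}
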