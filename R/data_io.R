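#' Construct an interaction dataset
#'
#' Bundles a binary targets-by-chemicals interaction matrix with its row
#' (protein target) and column (chemical) identifiers. A value of 1 marks a
#' known, experimentally verified interaction; 0 is ambiguous one-class data
#' (either no interaction or an untested pair).
#'
#' @param R numeric matrix with entries in \{0, 1\}; rows are targets,
#'   columns are chemicals. Dimnames, when present, supply the identifiers.
#' @param target_ids,chemical_ids optional character vectors overriding the
#'   dimnames of \code{R}.
#' @return An object of class \code{interaction_dataset} with elements
#'   \code{R}, \code{target_ids}, \code{chemical_ids}.
#' @examples
#' R <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("c1", "c2")))
#' interaction_dataset(R)
#' @export
interaction_dataset <- function(R, target_ids = NULL, chemical_ids = NULL) {
  R <- as.matrix(R)
  if (is.null(target_ids))   target_ids   <- rownames(R)
  if (is.null(chemical_ids)) chemical_ids <- colnames(R)
  if (is.null(target_ids))   target_ids   <- paste0("t", seq_len(nrow(R)))
  if (is.null(chemical_ids)) chemical_ids <- paste0("c", seq_len(ncol(R)))
  storage.mode(R) <- "double"
  if (nrow(R) < 1L || ncol(R) < 1L)
    stop("interaction matrix must have at least one row and one column")
  if (anyNA(R) || !all(R %in% c(0, 1)))
    stop("interaction matrix entries must all be 0 or 1")
  if (anyDuplicated(target_ids))
    stop("duplicate target identifiers: ",
         paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  if (anyDuplicated(chemical_ids))
    stop("duplicate chemical identifiers: ",
         paste(unique(chemical_ids[duplicated(chemical_ids)]), collapse = ", "))
  if (length(target_ids) != nrow(R) || length(chemical_ids) != ncol(R))
    stop("identifier lengths do not match matrix dimensions")
  dimnames(R) <- list(target_ids, chemical_ids)
  structure(list(R = R,
                 target_ids = as.character(target_ids),
                 chemical_ids = as.character(chemical_ids)),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("interaction_dataset: %d targets x %d chemicals, %d known interactions (density %.4f)\n",
              nrow(x$R), ncol(x$R), sum(x$R), mean(x$R)))
  invisible(x)
}

#' @export
dim.interaction_dataset <- function(x) dim(x$R)

#' Construct a validated similarity matrix
#'
#' Standardizes a square matrix of pairwise similarity scores (for example
#' normalized Smith-Waterman scores between protein sequences, or Tanimoto
#' scores between chemical fingerprints): the matrix is symmetrized as
#' \code{(S + t(S)) / 2}, entries are clipped to [0, 1] with a warning when
#' any clip occurs, and the diagonal is forced to 1 (self-similarity).
#'
#' @param S square numeric matrix; dimnames, when present, supply identifiers.
#' @param ids optional character vector of identifiers.
#' @return An object of class \code{similarity_matrix} with elements \code{S}
#'   (symmetric, values in [0, 1], unit diagonal) and \code{ids}.
#' @export
similarity_matrix <- function(S, ids = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != ncol(S))
    stop("similarity matrix must be square, got ", nrow(S), "x", ncol(S))
  if (is.null(ids)) ids <- rownames(S)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(S)))
  if (anyDuplicated(ids))
    stop("duplicate identifiers in similarity matrix")
  if (length(ids) != nrow(S))
    stop("identifier length does not match matrix dimension")
  if (anyNA(S) || any(!is.finite(S)))
    stop("similarity matrix contains non-finite values")
  asym <- max(abs(S - t(S)))
  if (asym > 1e-9)
    message(sprintf("symmetrizing similarity matrix (max asymmetry %.3g)", asym))
  S <- (S + t(S)) / 2
  n_clip <- sum(S < 0 | S > 1)
  if (n_clip > 0) {
    warning(sprintf("clipping %d similarity entries to [0, 1]", n_clip))
    S[S < 0] <- 0
    S[S > 1] <- 1
  }
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, ids = as.character(ids)), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf("similarity_matrix: %d entities, off-diagonal mean %.3f (range %.3f-%.3f)\n",
              nrow(x$S), mean(off), min(off), max(off)))
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$S)

read_table_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read an interaction matrix from a tab-delimited adjacency table
#'
#' The expected dialect is the one used by the public gold-standard
#' drug-target datasets: a header row of identifiers, a first column of
#' identifiers, and a 0/1 body. The \code{orientation} flag states which axis
#' the file's rows represent; the returned dataset is always oriented
#' targets-by-chemicals.
#'
#' @param path path to a tab-delimited file.
#' @param orientation \code{"rows_are_targets"} (default) or
#'   \code{"rows_are_chemicals"}.
#' @return An \code{\link{interaction_dataset}}.
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("rows_are_targets",
                                                    "rows_are_chemicals")) {
  orientation <- match.arg(orientation)
  X <- read_table_matrix(path)
  bad <- which(!(X %in% c(0, 1)) | is.na(X), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary cell at row '%s', column '%s' in %s",
                 rownames(X)[bad[1, 1]], colnames(X)[bad[1, 2]], path))
  if (orientation == "rows_are_chemicals") X <- t(X)
  interaction_dataset(X)
}

#' Write an interaction dataset as a tab-delimited adjacency table
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_interaction_matrix <- function(data, path) {
  stopifnot(inherits(data, "interaction_dataset"))
  write_table_matrix(data$R, path)
}

write_table_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from a tab-delimited table
#'
#' Reads a square similarity table, checks that the row and column identifier
#' sets match, optionally reorders to \code{id_order}, and runs the
#' standardization of \code{\link{similarity_matrix}} (symmetrization,
#' clipping, unit diagonal).
#'
#' @param path path to a tab-delimited file.
#' @param id_order optional identifier vector giving the desired order; every
#'   requested identifier must be present.
#' @return A \code{\link{similarity_matrix}}.
#' @export
read_similarity_matrix <- function(path, id_order = NULL) {
  S <- read_table_matrix(path)
  if (nrow(S) != ncol(S))
    stop("similarity table is not square: ", path)
  if (!setequal(rownames(S), colnames(S)))
    stop("row and column identifier sets differ in ", path)
  S <- S[, rownames(S), drop = FALSE]
  if (!is.null(id_order)) {
    missing_ids <- setdiff(id_order, rownames(S))
    if (length(missing_ids) > 0)
      stop("identifiers absent from similarity matrix: ",
           paste(missing_ids, collapse = ", "))
    S <- S[id_order, id_order, drop = FALSE]
  }
  similarity_matrix(S)
}

#' Write a similarity matrix as a tab-delimited table
#'
#' @param sim a \code{\link{similarity_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  write_table_matrix(sim$S, path)
}

#' Align interaction and similarity matrices to a common identifier order
#'
#' Subsets and reorders the target similarity matrix to the dataset's target
#' identifiers and the chemical similarity matrix to its chemical
#' identifiers. Every interaction identifier must have a similarity row: the
#' cold-start profile has nothing to work with otherwise, so absence is a
#' hard error rather than a silent zero fill.
#'
#' @param data an \code{\link{interaction_dataset}}.
#' @param target_sim,chem_sim \code{\link{similarity_matrix}} objects whose
#'   identifier sets are supersets of the dataset's targets and chemicals.
#' @return A list with elements \code{data}, \code{target_sim},
#'   \code{chem_sim}, all sharing identifier order with \code{data}.
#' @export
align_datasets <- function(data, target_sim, chem_sim) {
  stopifnot(inherits(data, "interaction_dataset"),
            inherits(target_sim, "similarity_matrix"),
            inherits(chem_sim, "similarity_matrix"))
  miss_t <- setdiff(data$target_ids, target_sim$ids)
  if (length(miss_t) > 0)
    stop("targets with no similarity row: ", paste(miss_t, collapse = ", "))
  miss_c <- setdiff(data$chemical_ids, chem_sim$ids)
  if (length(miss_c) > 0)
    stop("chemicals with no similarity row: ", paste(miss_c, collapse = ", "))
  M <- target_sim$S[data$target_ids, data$target_ids, drop = FALSE]
  N <- chem_sim$S[data$chemical_ids, data$chemical_ids, drop = FALSE]
  list(data = data,
       target_sim = similarity_matrix(M),
       chem_sim = similarity_matrix(N))
}
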