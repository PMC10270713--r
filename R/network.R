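#' Build a regional radiomics similarity network (R2SN)
#'
#' Constructs the per-subject, per-modality network whose nodes are the
#' atlas regions and whose edges are the Pearson correlations between the
#' regions' normalized, pruned radiomics feature vectors. The diagonal is
#' set to exactly 1.
#'
#' @param features a normalized (and typically pruned)
#'   `region_feature_matrix` with at least 2 retained features.
#' @return An object of class `r2sn`: list with `$adjacency` (symmetric
#'   `n x n` matrix, unit diagonal, entries in `[-1, 1]`), `$region_ids`,
#'   `$subject_id`, `$modality`.
#' @export
build_r2sn <- function(features) {
  stopifnot(inherits(features, "region_feature_matrix"))
  m <- features$matrix
  if (ncol(m) < 2L)
    stopf("need at least 2 retained features to correlate regions")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance feature vector for region(s): %s",
          paste(features$region_ids[sds == 0], collapse = ", "))
  a <- stats::cor(t(m))
  a <- (a + t(a)) / 2
  diag(a) <- 1
  structure(
    list(adjacency = a, region_ids = features$region_ids,
         subject_id = features$subject_id, modality = features$modality),
    class = "r2sn"
  )
}

r2sn_from_adjacency <- function(adjacency, region_ids = seq_len(nrow(adjacency)),
                                subject_id = NA_character_,
                                modality = NA_character_) {
  structure(
    list(adjacency = adjacency, region_ids = region_ids,
         subject_id = subject_id, modality = modality),
    class = "r2sn"
  )
}

#' @export
print.r2sn <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("R2SN: %d regions (%s, %s); edge range [%.3f, %.3f]\n",
              n, x$subject_id, x$modality,
              min(x$adjacency[upper.tri(x$adjacency)]),
              max(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

#' Vectorize the upper triangle of an R2SN
#'
#' Flattens the strictly-upper-triangular edges into a vector of length
#' `n(n-1)/2` in row-major order: `(1,2), (1,3), ..., (1,n), (2,3), ...`.
#' The order is fixed, so vectors are directly comparable across modalities
#' and subjects. For the standard 246-region atlas the vector has
#' 246*245/2 = 30135 entries.
#'
#' @param network an `r2sn` object or a symmetric matrix.
#' @param tol symmetry tolerance.
#' @return Numeric vector of edge weights.
#' @export
vectorize_upper <- function(network, tol = 1e-8) {
  a <- if (inherits(network, "r2sn")) network$adjacency else network
  if (max(abs(a - t(a))) > tol)
    stopf("adjacency is asymmetric beyond tolerance %g", tol)
  ta <- t(a)
  ta[lower.tri(ta)]               # row-major strict upper triangle of a
}

#' Rebuild a symmetric matrix from a row-major upper-triangle vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is filled with `diag`.
#'
#' @param v edge vector of length `n(n-1)/2`.
#' @param diag value for the diagonal (default 1).
#' @return Symmetric `n x n` matrix.
#' @export
unvectorize_upper <- function(v, diag = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9)
    stopf("length %d is not n(n-1)/2 for integer n", length(v))
  n <- as.integer(round(n))
  a <- matrix(0, n, n)
  a[lower.tri(a)] <- v            # fill column-major lower = row-major upper
  a <- t(a)
  a <- a + t(a)
  base::diag(a) <- diag
  a
}
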