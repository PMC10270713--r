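## Cross-modal coupling between a subject's two R2SNs.

check_aligned <- function(net_a, net_b) {
  if (!identical(net_a$region_ids, net_b$region_ids))
    stopf("networks have mismatched region sets or order")
}

#' Global coupling score between two R2SNs
#'
#' The Pearson correlation between the row-major upper-triangle edge
#' vectors of a subject's two modality networks (structural and
#' amyloid-PET). With 246 regions each vector has 30135 edges.
#'
#' @param net_a,net_b `r2sn` objects sharing region ids and order.
#' @return Scalar in `[-1, 1]`.
#' @seealso [local_coupling()], [coupling_profile()]
#' @export
global_coupling <- function(net_a, net_b) {
  check_aligned(net_a, net_b)
  va <- vectorize_upper(net_a)
  vb <- vectorize_upper(net_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stopf("zero-variance edge vector: global coupling undefined")
  stats::cor(va, vb)
}

#' Local (nodal) coupling scores between two R2SNs
#'
#' For each region i, the Pearson correlation between that region's
#' connection profile in the two networks: the n-1 off-diagonal entries of
#' row i. The unit self-connection is excluded, since a constant pair
#' carries no information.
#'
#' @inheritParams global_coupling
#' @return Numeric vector of length `n_regions`, named by region id.
#' @export
local_coupling <- function(net_a, net_b) {
  check_aligned(net_a, net_b)
  a <- net_a$adjacency
  b <- net_b$adjacency
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    xa <- a[i, -i]
    xb <- b[i, -i]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
      stopf("zero-variance connection profile for region %s",
            net_a$region_ids[i])
    out[i] <- stats::cor(xa, xb)
  }
  names(out) <- net_a$region_ids
  out
}

#' Per-subject coupling profile
#'
#' Bundles the global coupling score and the per-region local coupling
#' scores for one subject.
#'
#' @inheritParams global_coupling
#' @return Object of class `coupling_profile`: list with `$subject_id`,
#'   `$global_score`, `$local_scores`, `$region_ids`.
#' @export
coupling_profile <- function(net_a, net_b) {
  structure(
    list(subject_id = net_a$subject_id,
         global_score = global_coupling(net_a, net_b),
         local_scores = local_coupling(net_a, net_b),
         region_ids = net_a$region_ids),
    class = "coupling_profile"
  )
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat(sprintf(
    "Coupling profile %s: global = %.4f; local range [%.4f, %.4f] (%d regions)\n",
    x$subject_id, x$global_score, min(x$local_scores), max(x$local_scores),
    length(x$local_scores)))
  invisible(x)
}

#' Cohort coupling table
#'
#' Computes coupling profiles for a cohort and joins them to the subject
#' metadata, producing the analysis table consumed by the statistics and
#' survival modules: one row per subject with the global score, the local
#' scores (`local_<region>` columns in atlas-label order), demographics,
#' clinical measures and survival fields where present. Subjects missing a
#' modality are skipped with a warning and listed in the `qc` attribute.
#'
#' @param subjects list of subjects; each needs `$net_t1` and `$net_pet`
#'   (`r2sn` objects) plus `$metadata` (one-row data frame or named list)
#'   and optionally `$survival` (`time`, `event`).
#' @return A data frame; attribute `qc` is a data frame of skipped
#'   subjects and reasons.
#' @export
cohort_coupling_table <- function(subjects) {
  rows <- list()
  qc <- list()
  for (s in subjects) {
    sid <- s$metadata$subject_id %||% s$subject_id %||% NA_character_
    if (is.null(s$net_t1) || is.null(s$net_pet)) {
      miss <- paste(c(if (is.null(s$net_t1)) "T1",
                      if (is.null(s$net_pet)) "PET"), collapse = "+")
      qc[[length(qc) + 1L]] <- data.frame(
        subject_id = sid, reason = sprintf("missing modality: %s", miss))
      next
    }
    prof <- coupling_profile(s$net_t1, s$net_pet)
    loc <- as.list(prof$local_scores)
    names(loc) <- paste0("local_", prof$region_ids)
    meta <- as.data.frame(s$metadata, stringsAsFactors = FALSE)
    row <- cbind(meta,
                 data.frame(global_coupling = prof$global_score),
                 as.data.frame(loc))
    if (!is.null(s$survival)) {
      row$time <- s$survival$time
      row$event <- s$survival$event
    } else if (!is.null(s$metadata$time)) {
      # survival already inline in metadata
    } else {
      row$time <- NA_real_
      row$event <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stopf("no subject had both modalities")
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  qc_df <- if (length(qc)) do.call(rbind, qc) else
    data.frame(subject_id = character(0), reason = character(0))
  if (nrow(qc_df))
    warning(sprintf("%d subject(s) skipped; see attr(., 'qc')", nrow(qc_df)),
            call. = FALSE)
  attr(out, "qc") <- qc_df
  out
}
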