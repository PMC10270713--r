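## Regional radiomics feature extraction.
##
## All texture features operate on a fixed-bin quantization (32 bins spanning
## the region's own min-max) and are pooled over the 13 unique 3D directions
## at distance 1: the symmetric co-occurrence counts (GLCM) and the run
## counts (GLRLM) are accumulated across directions before the scalar
## features are computed, so each feature is a single direction-pooled value.

GLCM_BINS <- 32L

first_order_features <- function(x, ng = GLCM_BINS) {
  n <- length(x)
  m <- mean(x)
  v <- stats::var(x)                      # sample variance (n - 1)
  cm <- x - m
  m2 <- mean(cm^2)                        # population central moments for
  m3 <- mean(cm^3)                        # skewness / kurtosis
  m4 <- mean(cm^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0    # non-excess kurtosis
  p <- tabulate(quantize_bins(x, ng), nbins = ng) / n
  c(
    fo_mean = m,
    fo_median = stats::median(x),
    fo_sd = sqrt(v),
    fo_variance = v,
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = sum(x^2),
    fo_entropy = shannon_entropy(p),
    fo_min = min(x),
    fo_max = max(x),
    fo_range = max(x) - min(x),
    fo_mad = mean(abs(cm)),
    fo_rms = sqrt(mean(x^2)),
    fo_uniformity = sum(p^2)
  )
}

# Shape features of a voxel mask. Surface area is the exposed-face
# approximation (count of mask faces adjacent to background or the volume
# border), which makes a side-s cube measure exactly 6 s^2.
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  n <- sum(mask)
  vol <- n * prod(spacing)
  dims <- dim(mask)
  area <- 0
  face_area <- c(
    spacing[2] * spacing[3],
    spacing[1] * spacing[3],
    spacing[1] * spacing[2]
  )
  for (ax in 1:3) {
    pad_dim <- dims
    pad_dim[ax] <- dims[ax] + 2L
    padded <- array(FALSE, pad_dim)
    idx <- lapply(seq_along(dims), function(a) {
      if (a == ax) seq_len(dims[a]) + 1L else seq_len(dims[a])
    })
    padded[idx[[1]], idx[[2]], idx[[3]]] <- mask
    lo <- idx; lo[[ax]] <- lo[[ax]] - 1L
    hi <- idx; hi[[ax]] <- hi[[ax]] + 1L
    core <- padded[idx[[1]], idx[[2]], idx[[3]]]
    exposed <- sum(core & !padded[lo[[1]], lo[[2]], lo[[3]]]) +
      sum(core & !padded[hi[[1]], hi[[2]], hi[[3]]])
    area <- area + exposed * face_area[ax]
  }
  # max 3D diameter over surface voxel centres; interior voxels cannot
  # realize the maximum pairwise distance
  co <- which(mask, arr.ind = TRUE)
  surf <- surface_voxels(mask)
  pts <- sweep(co[surf, , drop = FALSE], 2L, spacing, `*`)
  diam <- if (nrow(pts) < 2L) 0 else {
    d2 <- 0
    g <- rowSums(pts^2)
    # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b, max over pairs
    cross <- tcrossprod(pts)
    d2 <- max(outer(g, g, `+`) - 2 * cross)
    sqrt(max(d2, 0))
  }
  r_equiv <- (3 * vol / (4 * pi))^(1 / 3)
  c(
    sh_volume = vol,
    sh_surface_area = area,
    sh_surface_to_volume = area / vol,
    sh_sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    sh_compactness1 = vol / (sqrt(pi) * area^1.5),
    sh_compactness2 = 36 * pi * vol^2 / area^3,
    sh_spherical_disproportion = area / (4 * pi * r_equiv^2),
    sh_max_diameter = diam
  )
}

surface_voxels <- function(mask) {
  dims <- dim(mask)
  co <- which(mask, arr.ind = TRUE)
  on_surface <- rep(FALSE, nrow(co))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- co
      nb[, ax] <- nb[, ax] + s
      out <- nb[, ax] < 1L | nb[, ax] > dims[ax]
      inside <- !out
      nb_val <- rep(FALSE, nrow(co))
      nb_val[inside] <- mask[nb[inside, , drop = FALSE]]
      on_surface <- on_surface | out | !nb_val
    }
  }
  on_surface
}

# Accumulate symmetric co-occurrence counts for a bin array (NA outside the
# region) over the 13 unique directions at distance 1.
glcm_counts <- function(bins, ng = GLCM_BINS) {
  dims <- dim(bins)
  dirs <- texture_directions()
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    i1 <- seq_len(dims[1] - abs(d[1])); i2 <- i1 + abs(d[1])
    j1 <- seq_len(dims[2] - abs(d[2])); j2 <- j1 + abs(d[2])
    k1 <- seq_len(dims[3] - abs(d[3])); k2 <- k1 + abs(d[3])
    if (length(i1) == 0L || length(j1) == 0L || length(k1) == 0L) next
    if (d[1] < 0) { tmp <- i1; i1 <- i2; i2 <- tmp }
    if (d[2] < 0) { tmp <- j1; j1 <- j2; j2 <- tmp }
    if (d[3] < 0) { tmp <- k1; k1 <- k2; k2 <- tmp }
    a <- bins[i1, j1, k1]
    b <- bins[i2, j2, k2]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * ng + b[ok]    # column-major cell index
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts + t(counts)                     # symmetrize
}

glcm_features <- function(bins, ng = GLCM_BINS) {
  cc <- glcm_counts(bins, ng)
  tot <- sum(cc)
  if (tot == 0) {
    # single-voxel region in every direction: no pairs; define the
    # degenerate matrix as all mass on the (1,1) cell
    cc[1, 1] <- 1
    tot <- 1
  }
  p <- cc / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)          # symmetric: mu_x == mu_y
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  corr <- if (sd_x > 0) {
    (sum(p * i * j) - mu_x^2) / sd_x^2
  } else 1                               # degenerate: perfectly predictable
  # diagonal-band marginals
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  c(
    glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_energy = sum(p^2),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_entropy = shannon_entropy(p),
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_cluster_shade = sum(p * (i + j - 2 * mu_x)^3),
    glcm_cluster_prominence = sum(p * (i + j - 2 * mu_x)^4),
    glcm_max_probability = max(p),
    glcm_sum_average = sum((2:(2 * ng)) * psum),
    glcm_sum_entropy = shannon_entropy(psum),
    glcm_difference_entropy = shannon_entropy(pdiff),
    glcm_inverse_difference = sum(p / (1 + abs(i - j)))
  )
}

# Enumerate maximal runs of equal bin value along one direction.
# Returns a matrix of run counts: rows = grey level, cols = run length.
glrlm_counts <- function(bins, ng = GLCM_BINS) {
  dims <- dim(bins)
  dirs <- texture_directions()
  nvox <- length(bins)
  ar <- array(seq_len(nvox), dims)
  co <- arrayInd(seq_len(nvox), dims)
  max_len <- max(dims)
  counts <- matrix(0, ng, max_len)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    # position along the line through each voxel: steps since line entry
    t_ax <- rep(Inf, nvox)
    for (ax in 1:3) {
      if (d[ax] == 1) t_ax <- pmin(t_ax, co[, ax] - 1L)
      else if (d[ax] == -1) t_ax <- pmin(t_ax, dims[ax] - co[, ax])
    }
    start <- co - outer(t_ax, d)
    line_id <- (start[, 3] - 1) * dims[1] * dims[2] +
      (start[, 2] - 1) * dims[1] + start[, 1]
    ord <- order(line_id, t_ax)
    v <- bins[ord]
    lid <- line_id[ord]
    n <- length(v)
    same <- c(FALSE, lid[-1] == lid[-n] & !is.na(v[-1]) & !is.na(v[-n]) &
      v[-1] == v[-n])
    run_start <- which(!same)
    run_len <- diff(c(run_start, n + 1L))
    run_val <- v[run_start]
    keep <- !is.na(run_val)
    if (!any(keep)) next
    idx <- (run_len[keep] - 1L) * ng + run_val[keep]
    counts <- counts + matrix(tabulate(idx, nbins = ng * max_len), ng, max_len)
  }
  counts
}

glrlm_features <- function(bins, ng = GLCM_BINS) {
  rm_ <- glrlm_counts(bins, ng)
  nr <- sum(rm_)
  np <- sum(!is.na(bins)) * nrow(texture_directions())
  g <- matrix(seq_len(ng), nrow(rm_), ncol(rm_))
  l <- matrix(seq_len(ncol(rm_)), nrow(rm_), ncol(rm_), byrow = TRUE)
  p <- rm_ / nr
  mu_l <- sum(p * l)
  c(
    glrlm_sre = sum(rm_ / l^2) / nr,
    glrlm_lre = sum(rm_ * l^2) / nr,
    glrlm_gln = sum(rowSums(rm_)^2) / nr,
    glrlm_rln = sum(colSums(rm_)^2) / nr,
    glrlm_rp = nr / np,
    glrlm_lgre = sum(rm_ / g^2) / nr,
    glrlm_hgre = sum(rm_ * g^2) / nr,
    glrlm_srlge = sum(rm_ / (g^2 * l^2)) / nr,
    glrlm_srhge = sum(rm_ * g^2 / l^2) / nr,
    glrlm_lrlge = sum(rm_ * l^2 / g^2) / nr,
    glrlm_lrhge = sum(rm_ * g^2 * l^2) / nr,
    glrlm_rlv = sum(p * (l - mu_l)^2)
  )
}

#' Extract regional radiomics features from a parcellated volume
#'
#' Computes the registry's feature vector for every region of an
#' integer-labelled parcellation, one row per region in ascending label
#' order. First-order features are computed from the region's intensity
#' values; shape features from the region mask; GLCM and GLRLM texture
#' features from a 32-bin fixed-width quantization of the region's
#' intensities, pooled over the 13 unique 3D directions at distance 1.
#'
#' @param volume 3D numeric array of voxel intensities.
#' @param parcellation 3D array of integer region labels, same shape as
#'   `volume`; 0 is background, regions are labelled `1..max`.
#' @param registry feature registry (default [feature_registry()]); may be a
#'   subset of the default rows.
#' @param spacing voxel spacing along each axis (default isotropic 1).
#' @param subject_id,modality identifiers carried into the result.
#' @return An object of class `region_feature_matrix`: a list with the
#'   `n_regions x n_features` matrix (`$matrix`), `$region_ids`,
#'   `$feature_names`, `$subject_id`, `$modality`, `$normalized`.
#' @seealso [minmax_normalize()], [prune_redundant_features()], [build_r2sn()]
#' @export
extract_region_features <- function(volume, parcellation,
                                    registry = feature_registry(),
                                    spacing = c(1, 1, 1),
                                    subject_id = NA_character_,
                                    modality = NA_character_) {
  if (!identical(dim(volume), dim(parcellation)))
    stopf("volume and parcellation shapes differ: (%s) vs (%s)",
          paste(dim(volume), collapse = "x"),
          paste(dim(parcellation), collapse = "x"))
  if (!is_integerish(parcellation))
    stopf("parcellation must contain integer labels")
  labs <- seq_len(max(parcellation))
  feats <- registry$name
  out <- matrix(NA_real_, length(labs), length(feats),
                dimnames = list(labs, feats))
  fam <- split(feats, registry$family[match(feats, registry$name)])
  for (r in labs) {
    sel <- which(parcellation == r)
    if (length(sel) == 0L) stopf("region label %d is empty", r)
    # bounding-box subarrays keep the texture passes cheap
    co <- arrayInd(sel, dim(volume))
    rng <- apply(co, 2L, range)
    sub_idx <- lapply(1:3, function(a) rng[1, a]:rng[2, a])
    vol_bb <- volume[sub_idx[[1]], sub_idx[[2]], sub_idx[[3]], drop = FALSE]
    par_bb <- parcellation[sub_idx[[1]], sub_idx[[2]], sub_idx[[3]],
                           drop = FALSE]
    dim(vol_bb) <- dim(par_bb) <- vapply(sub_idx, length, integer(1))
    mask <- par_bb == r
    x <- vol_bb[mask]
    vals <- c(
      if (length(fam$firstorder)) first_order_features(x),
      if (length(fam$shape)) shape_features(mask, spacing),
      if (length(fam$glcm) || length(fam$glrlm)) {
        bins <- array(NA_integer_, dim(mask))
        bins[mask] <- quantize_bins(x)
        c(if (length(fam$glcm)) glcm_features(bins),
          if (length(fam$glrlm)) glrlm_features(bins))
      }
    )
    out[as.character(r), ] <- vals[feats]
  }
  if (anyNA(out)) stopf("feature extraction produced missing values")
  structure(
    list(matrix = out, region_ids = labs, feature_names = feats,
         subject_id = subject_id, modality = modality, normalized = FALSE),
    class = "region_feature_matrix"
  )
}

#' @export
print.region_feature_matrix <- function(x, ...) {
  cat(sprintf(
    "Region feature matrix: %d regions x %d features (%s, %s)%s\n",
    nrow(x$matrix), ncol(x$matrix),
    x$subject_id, x$modality,
    if (x$normalized) ", min-max normalized" else ""
  ))
  invisible(x)
}

#' Min-max normalize a region feature matrix
#'
#' Rescales every feature column to `[0, 1]` across the regions of one
#' subject and one modality: `x' = (x - min) / (max - min)`, with the
#' minimum and maximum taken over regions. Normalization is performed
#' within subject and modality, never across subjects. Idempotent.
#'
#' @param features a `region_feature_matrix` from
#'   [extract_region_features()].
#' @return The same object with columns rescaled and `normalized = TRUE`.
#' @export
minmax_normalize <- function(features) {
  stopifnot(inherits(features, "region_feature_matrix"))
  m <- features$matrix
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  flat <- hi - lo <= 0
  if (any(flat))
    stopf("constant feature column(s), normalization undefined: %s",
          paste(colnames(m)[flat], collapse = ", "))
  features$matrix <- sweep(sweep(m, 2L, lo), 2L, hi - lo, `/`)
  features$normalized <- TRUE
  features
}

#' Remove redundant features by pairwise correlation
#'
#' Computes the feature-by-feature Pearson correlation over region rows
#' pooled across the supplied matrices and greedily drops features until no
#' retained pair has `|R|` above the threshold. At each step the feature
#' with the most above-threshold partners is dropped; ties drop the feature
#' latest in registry order. The retained set is intended to be computed
#' once on a reference cohort and then re-applied to new subjects with
#' [apply_feature_subset()], so all subjects share one feature space.
#'
#' @param matrices a `region_feature_matrix` or list of them (normalized).
#' @param threshold redundancy cut on `|R|`, in (0, 1); default 0.9.
#' @return A list with `retained` (feature names kept, registry order),
#'   `dropped` (names removed, in drop order) and `matrices` (the inputs
#'   restricted to the retained features).
#' @export
prune_redundant_features <- function(matrices, threshold = 0.9) {
  if (inherits(matrices, "region_feature_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  if (!(threshold > 0 && threshold < 1))
    stopf("threshold must be in (0, 1), got %g", threshold)
  pooled <- do.call(rbind, lapply(matrices, `[[`, "matrix"))
  feats <- colnames(pooled)
  cc <- abs(stats::cor(pooled))
  diag(cc) <- 0
  keep <- rep(TRUE, length(feats))
  dropped <- character(0)
  repeat {
    hot <- cc > threshold & outer(keep, keep, `&`)
    deg <- rowSums(hot)
    if (max(deg) == 0) break
    victim <- max(which(deg == max(deg)))   # tie: drop latest in order
    keep[victim] <- FALSE
    dropped <- c(dropped, feats[victim])
  }
  list(
    retained = feats[keep],
    dropped = dropped,
    threshold = threshold,
    matrices = lapply(matrices, apply_feature_subset, retained = feats[keep])
  )
}

#' Restrict a feature matrix to a retained feature set
#'
#' Re-applies a previously computed pruning result to a new subject's
#' feature matrix without recomputing correlations.
#'
#' @param features a `region_feature_matrix`.
#' @param retained character vector of feature names to keep.
#' @return The restricted `region_feature_matrix`.
#' @export
apply_feature_subset <- function(features, retained) {
  stopifnot(inherits(features, "region_feature_matrix"))
  missing_f <- setdiff(retained, features$feature_names)
  if (length(missing_f))
    stopf("features not present: %s", paste(missing_f, collapse = ", "))
  keep <- features$feature_names[features$feature_names %in% retained]
  features$matrix <- features$matrix[, keep, drop = FALSE]
  features$feature_names <- keep
  features
}
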