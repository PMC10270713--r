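## Covariate-adjusted group contrasts, biomarker subgroups and clinical
## correlations.
##
## "Test with covariates" is implemented as residualize-then-test: scores
## are replaced by the residuals of an OLS fit on [intercept, covariates]
## over complete cases, and the plain test runs on the residuals. For the
## two-group t this is numerically near-identical to the group coefficient
## of an ANCOVA.

covariate_design <- function(table, covariates) {
  x <- matrix(1, nrow(table), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- table[[cv]]
    if (is.null(v)) stopf("covariate '%s' not found", cv)
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) > 1L)
        for (l in lev[-1]) x <- cbind(x, as.numeric(v == l))
      else
        x <- cbind(x, 0)  # single level: constant column, caught below
    } else {
      x <- cbind(x, as.numeric(v))
    }
  }
  x
}

#' Residualize values on covariates
#'
#' Returns the residuals of an ordinary least-squares fit of `values` on an
#' intercept plus the covariate columns of `table` (character/factor
#' covariates are indicator-coded). Rows with missing values or covariates
#' are dropped (listwise deletion); the result carries the retained row
#' indices as the `rows` attribute.
#'
#' @param values numeric vector.
#' @param table data frame holding the covariate columns.
#' @param covariates character vector of covariate column names
#'   (default `c("age", "sex")`).
#' @return Numeric residual vector over complete cases, with attribute
#'   `rows` giving the original row indices used.
#' @export
adjust_for_covariates <- function(values, table, covariates = c("age", "sex")) {
  x <- covariate_design(table, covariates)
  ok <- stats::complete.cases(values, x)
  xc <- x[ok, , drop = FALSE]
  y <- values[ok]
  if (length(y) < ncol(xc) + 2L)
    stopf("too few complete cases (%d) for %d parameters", length(y), ncol(xc))
  qx <- qr(xc)
  if (qx$rank < ncol(xc))
    stopf("rank-deficient covariate design (constant or collinear column)")
  res <- qr.resid(qx, y)
  attr(res, "rows") <- which(ok)
  res
}

pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  tt <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' One-way ANOVA on covariate-residualized scores
#'
#' Tests whether a score differs among the diagnostic groups after
#' residualizing on the covariates.
#'
#' @param table data frame with the score, group and covariate columns.
#' @param score name of the score column (default `"global_coupling"`).
#' @param covariates covariate column names; `NULL` or empty for none.
#' @param group name of the grouping column.
#' @return A `contrast_result` list: `$contrast`, `$statistic` (F),
#'   `$df`, `$p`, `$n`, `$covariates`.
#' @export
group_anova <- function(table, score = "global_coupling",
                        covariates = c("age", "sex"), group = "group") {
  res <- residual_scores(table, score, covariates)
  g <- factor(table[[group]][attr(res, "rows")])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stopf("need >= 2 groups with n >= 2 each")
  fit <- stats::aov(res ~ g)
  sm <- summary(fit)[[1]]
  structure(
    list(contrast = paste(levels(g), collapse = " vs "),
         statistic = sm$`F value`[1], df = sm$Df,
         p = sm$`Pr(>F)`[1], n = length(res),
         covariates = covariates, method = "anova"),
    class = "contrast_result"
  )
}

residual_scores <- function(table, score, covariates) {
  v <- table[[score]]
  if (is.null(v)) stopf("score column '%s' not found", score)
  if (length(covariates)) {
    adjust_for_covariates(v, table, covariates)
  } else {
    ok <- which(!is.na(v))
    structure(v[ok] - mean(v[ok]), rows = ok)
  }
}

#' Two-sample t test on covariate-residualized scores
#'
#' Two-tailed pooled-variance t test comparing a score between two groups,
#' after residualizing on the covariates within the two-group subsample.
#' The sign of t follows `mean(g1) - mean(g2)`.
#'
#' @inheritParams group_anova
#' @param groups length-2 character vector `(g1, g2)`.
#' @return A `contrast_result` with `$statistic` (t), `$df`, `$p`.
#' @export
pairwise_t <- function(table, score = "global_coupling", groups,
                       covariates = c("age", "sex"), group = "group") {
  stopifnot(length(groups) == 2L)
  sub <- table[table[[group]] %in% groups, , drop = FALSE]
  res <- residual_scores(sub, score, covariates)
  g <- sub[[group]][attr(res, "rows")]
  if (sum(g == groups[1]) < 2L || sum(g == groups[2]) < 2L)
    stopf("each group needs n >= 2")
  tt <- pooled_t(res[g == groups[1]], res[g == groups[2]])
  structure(
    list(contrast = paste(groups, collapse = " vs "),
         statistic = tt$t, df = tt$df, p = tt$p, n = length(res),
         covariates = covariates, method = "pooled t"),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s (%s%s): statistic = %.3f, p = %.3g, n = %d\n",
              x$contrast, x$method,
              if (length(x$covariates))
                paste0(", adj. ", paste(x$covariates, collapse = "+"))
              else "",
              x$statistic[1], x$p, x$n))
  invisible(x)
}

#' Region-wise group contrast with Bonferroni control
#'
#' Runs the covariate-residualized pooled t test for every local coupling
#' column and flags regions significant at the Bonferroni-corrected
#' threshold `alpha / n_regions` (0.05 / 246 = 2.0325e-4 for the default
#' atlas). Results can be sorted by `|t|` to list the top discriminative
#' regions.
#'
#' @inheritParams pairwise_t
#' @param region_cols names of the per-region score columns; default all
#'   columns starting with `"local_"`.
#' @param alpha family-wise error target (default 0.05).
#' @return A `contrast_result` whose `$regions` is a data frame with one
#'   row per region: `region`, `t`, `p`, `significant`.
#' @export
local_contrast <- function(table, groups, covariates = c("age", "sex"),
                           group = "group",
                           region_cols = grep("^local_", names(table),
                                              value = TRUE),
                           alpha = 0.05) {
  stopifnot(length(groups) == 2L, length(region_cols) >= 1L)
  sub <- table[table[[group]] %in% groups, , drop = FALSE]
  x <- covariate_design(sub, covariates)
  y <- as.matrix(sub[, region_cols, drop = FALSE])
  ok <- stats::complete.cases(y, x)
  xc <- x[ok, , drop = FALSE]
  if (qr(xc)$rank < ncol(xc)) stopf("rank-deficient covariate design")
  res <- qr.resid(qr(xc), y[ok, , drop = FALSE])
  g <- sub[[group]][ok]
  i1 <- g == groups[1]; i2 <- g == groups[2]
  if (sum(i1) < 2L || sum(i2) < 2L) stopf("each group needs n >= 2")
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(res[i1, , drop = FALSE])
  m2 <- colMeans(res[i2, , drop = FALSE])
  v1 <- apply(res[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(res[i2, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  thr <- alpha / length(region_cols)
  regions <- data.frame(
    region = sub("^local_", "", region_cols),
    t = unname(tt), p = unname(p),
    significant = unname(p < thr),
    stringsAsFactors = FALSE
  )
  structure(
    list(contrast = paste(groups, collapse = " vs "),
         statistic = NA_real_, p = NA_real_, n = n1 + n2,
         covariates = covariates, method = "region-wise pooled t",
         p_threshold = thr, regions = regions),
    class = "contrast_result"
  )
}

#' Derive biomarker positivity statuses from CSF values
#'
#' Adds `abeta_status` (positive iff CSF A-beta < 980 pg/ml) and
#' `tau_status` (positive iff CSF total Tau > 245 pg/ml) columns; strict
#' inequalities, so boundary values classify negative. Missing CSF values
#' propagate to `NA` (unknown) status.
#'
#' @param table data frame with `csf_abeta` and/or `csf_tau` columns.
#' @return The table with status columns added.
#' @export
biomarker_subgroups <- function(table) {
  for (cn in c("csf_abeta", "csf_tau"))
    if (!is.null(table[[cn]]) && any(table[[cn]] < 0, na.rm = TRUE))
      stopf("negative values in %s", cn)
  if (!is.null(table$csf_abeta))
    table$abeta_status <- ifelse(is.na(table$csf_abeta), NA_character_,
      ifelse(table$csf_abeta < CSF_ABETA_CUTOFF, "positive", "negative"))
  if (!is.null(table$csf_tau))
    table$tau_status <- ifelse(is.na(table$csf_tau), NA_character_,
      ifelse(table$csf_tau > CSF_TAU_CUTOFF, "positive", "negative"))
  table
}

#' Partial correlations between coupling and clinical measures
#'
#' For each measure, computes the partial Pearson correlation with the
#' score by residualizing both sides on the covariates over that measure's
#' complete cases (double residualization), with significance at the
#' Bonferroni threshold `alpha / n_measures` (0.05/9 for the default
#' clinical battery).
#'
#' @inheritParams group_anova
#' @param measures character vector of measure column names; default the
#'   nine-measure battery (MMSE, AVLT1/2, ADAS-cog11/13, CSF A-beta, CSF
#'   Tau, CSF p-Tau, FDG).
#' @param alpha family-wise error target.
#' @return Data frame with one row per measure: `measure`, `r`, `p`, `n`,
#'   `significant`; attribute `p_threshold`.
#' @export
clinical_correlations <- function(table, score = "global_coupling",
                                  measures = c("mmse", "avlt1", "avlt2",
                                               "adas11", "adas13",
                                               "csf_abeta", "csf_tau",
                                               "csf_ptau", "fdg"),
                                  covariates = c("age", "sex"),
                                  alpha = 0.05) {
  thr <- alpha / length(measures)
  out <- lapply(measures, function(ms) {
    v <- table[[ms]]
    if (is.null(v)) stopf("measure column '%s' not found", ms)
    x <- covariate_design(table, covariates)
    sc <- table[[score]]
    ok <- stats::complete.cases(v, sc, x)
    n <- sum(ok)
    if (n < 4L) stopf("fewer than 4 complete cases for '%s'", ms)
    xc <- x[ok, , drop = FALSE]
    qx <- qr(xc)
    if (qx$rank < ncol(xc)) stopf("rank-deficient covariate design")
    r1 <- qr.resid(qx, v[ok])
    r2 <- qr.resid(qx, sc[ok])
    r <- stats::cor(r1, r2)
    df <- n - 2L - (ncol(xc) - 1L)   # df loss: 2 + number of covariates
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(measure = ms, r = r, p = p, n = n, significant = p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "p_threshold") <- thr
  out
}
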