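## Coupling-stratified Kaplan-Meier analysis of MCI-to-AD conversion.

#' Stratify subjects by global coupling score
#'
#' Splits subjects at the empirical median (`"halves"`) or quartiles
#' (`"quartiles"`) of their coupling scores. Ties at a cut point go to the
#' lower stratum. S1 is the lowest-coupling stratum (0-25%), S4 the
#' highest; halves are labelled `low` / `high`.
#'
#' @param scores numeric coupling scores.
#' @param scheme `"halves"` or `"quartiles"`.
#' @return Factor of stratum labels, same length as `scores`.
#' @export
stratify_by_coupling <- function(scores, scheme = c("halves", "quartiles")) {
  scheme <- match.arg(scheme)
  if (any(is.na(scores))) stopf("scores contain missing values")
  if (length(unique(scores)) < 2L)
    stopf("all coupling scores equal: stratification undefined")
  if (scheme == "halves") {
    q <- stats::quantile(scores, 0.5, names = FALSE)
    factor(ifelse(scores > q, "high", "low"), levels = c("low", "high"))
  } else {
    if (length(scores) < 4L) stopf("need >= 4 subjects for quartiles")
    q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
    lev <- paste0("S", 1:4)
    idx <- 1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
    factor(lev[idx], levels = lev)
  }
}

#' Kaplan-Meier curves per stratum
#'
#' Product-limit survival estimates `S(t) = prod(1 - d_i / n_i)` over the
#' distinct event times of each group, computed with
#' [survival::survfit()]. With no censoring `S` equals one minus the
#' empirical CDF of the event times.
#'
#' @param time follow-up durations (months), positive.
#' @param event 1 = converted to AD, 0 = censored.
#' @param group stratum labels.
#' @return A data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, including the `t = 0, S = 1` anchor per group.
#' @export
km_estimate <- function(time, event, group) {
  if (any(time <= 0)) stopf("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  g <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = g, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  anchors <- data.frame(group = levels(group), time = 0,
                        n_risk = as.vector(table(group)), n_event = 0,
                        surv = 1, stringsAsFactors = FALSE)
  out <- rbind(anchors, curves)
  out <- out[order(out$group, out$time), ]
  rownames(out) <- NULL
  out
}

#' Log-rank tests between strata
#'
#' Standard log-rank chi-square via [survival::survdiff()]; with
#' `pairwise = TRUE` all 1-df pairwise comparisons are returned (six for
#' the quartile scheme), uncorrected.
#'
#' @inheritParams km_estimate
#' @param pairwise if `TRUE`, test every pair of strata; otherwise one
#'   overall test.
#' @return Data frame with `group1`, `group2` (NA for the overall test),
#'   `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group, pairwise = FALSE) {
  if (sum(event) == 0) stopf("no events: log-rank test undefined")
  group <- factor(group)
  one <- function(sel, g1, g2) {
    sd_ <- survival::survdiff(
      survival::Surv(time[sel], event[sel]) ~ droplevels(group[sel]))
    df <- length(sd_$n) - 1L
    data.frame(group1 = g1, group2 = g2, chisq = sd_$chisq, df = df,
               p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  if (!pairwise)
    return(one(rep(TRUE, length(time)), NA_character_, NA_character_))
  lev <- levels(group)
  pairs <- utils::combn(lev, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- group %in% c(g1, g2)
    if (sum(event[sel]) == 0)
      return(data.frame(group1 = g1, group2 = g2, chisq = NA_real_,
                        df = 1L, p = NA_real_, stringsAsFactors = FALSE))
    one(sel, g1, g2)
  })
  do.call(rbind, out)
}
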