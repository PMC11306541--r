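#' Spearman association of kinase activity with overall survival
#'
#' Per kinase, the Spearman correlation between per-sample INKA scores and
#' overall survival in months (exact p for small n without ties, t
#' approximation otherwise, as implemented in [stats::cor.test()]). OS is
#' correlated directly, without censoring adjustment; a caveat is attached
#' when censored samples enter. Kinases observed in fewer than 3 samples are
#' skipped; constant score vectors are reported not-assessable (`NA`).
#'
#' @param smat kinase-by-sample INKA score matrix.
#' @param clinical clinical table (`sample_id`, `os_months`, `event_flag`,
#'   `treatment_naive`).
#' @param naive_only restrict to treatment-naive patients.
#' @return data.frame of class `SurvivalAssoc`: `kinase`, `rho`, `p`,
#'   `n_used`, `direction` (`"poor"` for negative rho: higher activity,
#'   shorter survival).
#' @export
spearman_survival <- function(smat, clinical, naive_only = FALSE) {
  cl <- clinical
  if (naive_only) cl <- cl[cl$treatment_naive == 1, , drop = FALSE]
  common <- intersect(colnames(smat), cl$sample_id)
  os <- cl$os_months[match(common, cl$sample_id)]
  rows <- lapply(rownames(smat), function(k) {
    x <- smat[k, common]
    ok <- !is.na(x)
    if (sum(ok) < 3L) return(NULL)
    xo <- x[ok]; oso <- os[ok]
    if (sd(xo) == 0)
      return(data.frame(kinase = k, rho = NA_real_, p = NA_real_,
                        n_used = sum(ok), direction = "not-assessable",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(xo, oso, method = "spearman"))
    rho <- unname(ct$estimate)
    data.frame(kinase = k, rho = rho, p = ct$p.value, n_used = sum(ok),
               direction = if (rho < 0) "poor" else "favorable",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    if (any(cl$event_flag[match(common, cl$sample_id)] == 0))
      attr(out, "caveat") <-
        "censored samples included; OS correlated without censoring adjustment"
    class(out) <- c("SurvivalAssoc", "data.frame")
  }
  out
}

#' Bimodal cutoff on an overall-survival distribution
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth, 512-point
#' grid) on the OS values; with two or more modes, the cutoff is the
#' position of the lowest density minimum between the two largest modes;
#' unimodal distributions return `NA`.
#'
#' @param os overall survival in months (n >= 10).
#' @param n_grid density grid size.
#' @return Cutoff in months, or `NA` if unimodal.
#' @export
bimodal_cutoff <- function(os, n_grid = 512L) {
  os <- os[!is.na(os)]
  if (length(os) < 10L)
    stop("need at least 10 survival times; set a manual cutoff instead")
  d <- density(os, bw = "nrd0", n = n_grid)
  y <- d$y
  i <- 2:(length(y) - 1L)
  maxima <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  if (length(maxima) < 2L) return(NA_real_)
  top2 <- sort(maxima[order(-y[maxima])][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Short- and long-survival outcome groups
#'
#' Splits (by default treatment-naive) patients at the OS cutoff: long
#' survivors have `os_months > cutoff`, short survivors `os_months <=
#' cutoff`.
#'
#' @param clinical clinical table.
#' @param cutoff OS cutoff in months (> 0).
#' @param naive_only restrict to treatment-naive patients (default TRUE).
#' @return List of class `OutcomeGroups`: `cutoff_months`, `short_ids`,
#'   `long_ids`, `treatment_naive_only`.
#' @export
define_outcome_groups <- function(clinical, cutoff, naive_only = TRUE) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  cl <- clinical
  if (naive_only) cl <- cl[cl$treatment_naive == 1, , drop = FALSE]
  short_ids <- cl$sample_id[cl$os_months <= cutoff]
  long_ids <- cl$sample_id[cl$os_months > cutoff]
  if (!length(short_ids) || !length(long_ids))
    stop("empty outcome group at cutoff ", cutoff)
  structure(list(cutoff_months = cutoff, short_ids = short_ids,
                 long_ids = long_ids, treatment_naive_only = naive_only),
            class = "OutcomeGroups")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function and the median
#' survival; censoring handled in the usual way (risk-set decrement without
#' an event step).
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return List with `time`, `surv` (step function values at the event
#'   times), `n_risk`, `n_event` and `median` (`NA` = not reached).
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Two-group log-rank test
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param group two-level group labels.
#' @return List with `chisq` (1 dof) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank test here expects exactly 2 groups")
  if (length(unique(times)) == 1L && length(unique(events)) == 1L)
    return(list(chisq = 0, p = 1))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Differential features between extreme-outcome groups
#'
#' Moderated two-group test (short vs long survivors) gated on unadjusted
#' p <= `p_max` and |log2 FC| >= log2(`fc_min`) — the small extreme-group
#' contrast deliberately uses raw p, unlike the FDR-gated subtype analysis.
#'
#' @param m feature-by-sample log2 matrix or `SiteMatrix`.
#' @param groups an `OutcomeGroups`.
#' @param p_max unadjusted p threshold (default 0.05, inclusive).
#' @param fc_min fold-change threshold (default 2, inclusive).
#' @return List with the full `DiffResult` (`$result`) and the significant
#'   feature ids (`$significant`); log2 FC is short minus long.
#' @export
extreme_group_diff <- function(m, groups, p_max = 0.05, fc_min = 2.0) {
  stopifnot(inherits(groups, "OutcomeGroups"))
  mat <- as_feature_matrix(m)
  ids <- c(groups$long_ids, groups$short_ids)
  ids <- intersect(colnames(mat), ids)
  if (length(intersect(ids, groups$short_ids)) < 2L ||
      length(intersect(ids, groups$long_ids)) < 2L)
    stop("need at least 2 samples per outcome group")
  labs <- setNames(ifelse(ids %in% groups$short_ids, "short", "long"), ids)
  labs <- factor(labs, levels = c("long", "short"))  # lfc = short - long
  res <- moderated_test(mat[, ids, drop = FALSE], labs)
  sig <- significant_features(res, q_max = p_max, fc_min = fc_min,
                              use_q = FALSE)
  list(result = res, significant = sig)
}
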