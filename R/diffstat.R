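#' Moderated differential test (empirical-Bayes variance shrinkage)
#'
#' Two-group moderated t or multi-group moderated F on log2 intensities.
#' Per-feature pooled variances s2_g with residual dof d_g are shrunk toward
#' a prior (d0, s0^2) fitted by moment matching on log s2_g across features
#' (Smyth-style): the posterior variance is
#' `(d0 * s0^2 + d_g * s2_g) / (d0 + d_g)` and the statistic gains d0 prior
#' dof. Features are tested on observed values only; a feature needs at
#' least 2 observed values per group, otherwise it is reported untested.
#'
#' @param m feature-by-sample matrix (log2, `NA` = missing) or `SiteMatrix`.
#' @param groups factor/vector of group labels, one per sample (or a named
#'   vector matched against the sample names).
#' @param d0 optional prior-dof override; `d0 = 0` recovers the classic
#'   unpaired test, `d0 = Inf` fully shrinks every variance to `s0^2`.
#' @param s02 optional prior-variance override (used with `d0`).
#' @return A data.frame of class `DiffResult` with per-feature group means,
#'   `log2_fc` (two groups: mean of second level minus mean of first; more
#'   groups: largest pairwise difference), `stat`, `p`, `q` (BH-adjusted),
#'   `s2_g`, `d_g`, `tested`; fitted `d0` and `s0_2` are attached as
#'   attributes.
#' @export
moderated_test <- function(m, groups, d0 = NULL, s02 = NULL) {
  mat <- as_feature_matrix(m)
  if (!is.null(names(groups)) && !is.null(colnames(mat)))
    groups <- groups[colnames(mat)]
  g <- factor(groups)
  if (length(g) != ncol(mat))
    stop("groups must have one label per sample")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  lev <- levels(g)
  k <- nlevels(g)
  for (l in lev)
    if (!any(rowSums(!is.na(mat[, g == l, drop = FALSE])) > 0))
      stop("group '", l, "' has no observed values for any feature")

  nf <- nrow(mat)
  means <- matrix(NA_real_, nf, k, dimnames = list(rownames(mat), lev))
  ns <- matrix(0L, nf, k)
  ss <- matrix(0, nf, k)
  for (j in seq_len(k)) {
    sub <- mat[, g == lev[j], drop = FALSE]
    ns[, j] <- rowSums(!is.na(sub))
    means[, j] <- rowMeans(sub, na.rm = TRUE)
    ctr <- sub - means[, j]
    ss[, j] <- rowSums(ctr^2, na.rm = TRUE)
  }
  tested <- rowSums(ns >= 2L) == k
  d_g <- rowSums(ns) - k
  s2_g <- rowSums(ss) / pmax(d_g, 1)

  fit_ok <- tested & d_g > 0 & s2_g > 0
  if (is.null(d0)) {
    fit <- fit_variance_prior(s2_g[fit_ok], d_g[fit_ok])
    d0 <- fit$d0
    s02 <- fit$s0_2
    if (!is.finite(s02) || is.na(d0)) {
      warning("variance prior fit failed; falling back to classic test")
      d0 <- 0
      s02 <- mean(s2_g[fit_ok])
    }
  } else if (is.null(s02)) {
    s02 <- mean(s2_g[fit_ok])
  }

  s2_post <- if (is.infinite(d0)) rep(s02, nf)
             else (d0 * s02 + d_g * s2_g) / (d0 + d_g)
  df_total <- d0 + d_g

  if (k == 2L) {
    lfc <- means[, 2] - means[, 1]
    se <- sqrt(s2_post * (1 / ns[, 1] + 1 / ns[, 2]))
    stat <- lfc / se
    p <- 2 * pt(-abs(stat), df_total)
  } else {
    grand <- rowSums(means * ns) / rowSums(ns)
    msb <- rowSums(ns * (means - grand)^2) / (k - 1)
    stat <- msb / s2_post
    p <- pf(stat, k - 1, df_total, lower.tail = FALSE)
    # fold-change gate for >2 groups uses the largest pairwise difference
    lfc <- apply(means, 1, function(x) max(x) - min(x))
  }
  stat[!tested] <- NA_real_
  p[!tested] <- NA_real_
  lfc[!tested] <- NA_real_
  q <- rep(NA_real_, nf)
  q[tested] <- bh_adjust(pmax(p[tested], .Machine$double.xmin))

  res <- data.frame(feature = rownames(mat) %||% as.character(seq_len(nf)),
                    means, log2_fc = lfc, stat = stat, p = p, q = q,
                    s2_g = s2_g, d_g = d_g, tested = tested,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s02
  attr(res, "levels") <- lev
  class(res) <- c("DiffResult", "data.frame")
  res
}

# Moment-matching fit of the scaled inverse-chi-square variance prior:
# z = log s2_g; E[z] and Var[z] involve digamma/trigamma of the dofs, so the
# excess variance of z over its sampling part identifies d0, and the mean
# identifies s0^2.
fit_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2L) return(list(d0 = NA_real_, s0_2 = NA_real_))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  uniroot(function(x) trigamma(x) - y, lower = 1e-8, upper = 1e8,
          tol = 1e-12)$root
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order preserved on return.
#'
#' @param p p-values in (0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Significant features under FDR and fold-change gates
#'
#' Boundary inclusive on both gates: `q <= q_max` and
#' `|log2_fc| >= log2(fc_min)`.
#'
#' @param res a `DiffResult`.
#' @param q_max FDR threshold (default 0.05). Set `use_q = FALSE` to gate on
#'   unadjusted p instead (extreme-outcome contrasts).
#' @param fc_min ratio-scale fold-change threshold (default 2, i.e.
#'   |log2 FC| >= 1).
#' @param use_q gate on `q` (default) or raw `p`.
#' @return Character vector of significant feature ids.
#' @export
significant_features <- function(res, q_max = 0.05, fc_min = 2.0,
                                 use_q = TRUE) {
  stopifnot(inherits(res, "DiffResult"))
  crit <- if (use_q) res$q else res$p
  ok <- res$tested & !is.na(crit) & crit <= q_max &
    abs(res$log2_fc) >= log2(fc_min)
  res$feature[ok]
}

#' Signed -log10 p rank metric
#'
#' `r = -log10(p) * sign(log2_fc)`, with `sign(0) = 0`; the pre-ranked input
#' for enrichment. p-values of 0 are capped at the smallest representable
#' double with a warning.
#'
#' @param res a `DiffResult` (or a data.frame with `p` and `log2_fc`).
#' @return Named numeric vector keyed by feature.
#' @export
rank_metric <- function(res) {
  p <- res$p
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-values of 0 capped at the machine minimum")
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  r <- -log10(p) * sign(res$log2_fc)
  setNames(r, res$feature)[!is.na(r)]
}

#' Non-parametric group tests
#'
#' Mann-Whitney (two groups; exact when both groups have <= 8 observations
#' and no ties, normal approximation with tie correction otherwise) and
#' Kruskal-Wallis (any number of groups, chi-square p).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return List with `method`, `statistic` and `p`.
#' @export
nonparametric_tests <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) == 0L) || nlevels(g) < 2L)
    stop("need at least 2 non-empty groups")
  keep <- !is.na(values)
  values <- values[keep]; g <- droplevels(g[keep])
  if (any(table(g) < 1L)) stop("empty group after removing missing values")
  if (nlevels(g) == 2L) {
    x <- values[g == levels(g)[1]]
    y <- values[g == levels(g)[2]]
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = !exact))
    list(method = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value)
  } else {
    kt <- kruskal.test(values, g)
    list(method = "kruskal-wallis", statistic = unname(kt$statistic),
         p = kt$p.value)
  }
}
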