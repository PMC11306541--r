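#' Median-site normalization (global pS/T channel)
#'
#' Scales each sample's observed intensities multiplicatively so its median
#' observed site intensity equals the across-sample median of per-sample
#' medians. Missing entries stay missing. Any fixed target would only change
#' a global constant; the median-of-medians keeps the data on its own scale.
#'
#' @param m a `SiteMatrix` with channel `global_pST`.
#' @return The normalized `SiteMatrix`; scale factors in attribute
#'   `"scale_factors"`.
#' @export
normalize_median_site <- function(m) {
  stopifnot(inherits(m, "SiteMatrix"))
  if (m$channel != "global_pST")
    stop("median-site normalization applies to the global_pST channel")
  med <- apply(m$intensity, 2, median, na.rm = TRUE)
  none <- colSums(!is.na(m$intensity)) == 0L
  if (any(none))
    stop("sample(s) with zero observed values: ",
         paste(samples_of(m)[none], collapse = ", "))
  target <- median(med)
  sf <- target / med
  m$intensity <- sweep(m$intensity, 2, sf, `*`)
  attr(m, "scale_factors") <- sf
  m
}

#' Total-lysate-count normalization (pY channel)
#'
#' Scales each pY sample by (mean of lysate spectral-count totals) /
#' (sample's own total), so samples with deeper lysate coverage are shrunk
#' toward the cohort average.
#'
#' @param m a `SiteMatrix` with channel `pY`.
#' @param lysate_counts named numeric vector of per-sample total lysate
#'   spectral counts; must cover every pY sample with a positive value.
#' @return The normalized `SiteMatrix`.
#' @export
normalize_total_count <- function(m, lysate_counts) {
  stopifnot(inherits(m, "SiteMatrix"))
  if (m$channel != "pY")
    stop("total-count normalization applies to the pY channel")
  s <- samples_of(m)
  tot <- lysate_counts[s]
  bad <- is.na(tot) | tot <= 0
  if (any(bad))
    stop("missing or non-positive lysate total for sample(s): ",
         paste(s[bad], collapse = ", "))
  sf <- mean(tot) / tot
  m$intensity <- sweep(m$intensity, 2, sf, `*`)
  attr(m, "scale_factors") <- sf
  m
}

as_feature_matrix <- function(m) {
  if (inherits(m, "SiteMatrix")) m$intensity else as.matrix(m)
}

rewrap <- function(m, mat, keep = NULL) {
  if (inherits(m, "SiteMatrix")) {
    if (!is.null(keep)) m <- subset_sites(m, keep)
    m$intensity <- mat
    m
  } else mat
}

#' Data-presence (DP) filtering
#'
#' Keeps features observed (non-missing, non-zero) in at least `fraction` of
#' samples, boundary inclusive. `fraction = 1` retains complete features
#' only.
#'
#' @param m a `SiteMatrix` or plain feature-by-sample matrix (`NA` missing).
#' @param fraction required observed fraction in (0, 1].
#' @return Object of the same kind with failing features removed.
#' @export
filter_data_presence <- function(m, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  mat <- as_feature_matrix(m)
  obs <- rowSums(!is.na(mat) & mat != 0) / ncol(mat)
  keep <- obs >= fraction
  rewrap(m, mat[keep, , drop = FALSE], keep)
}

#' Select the most variable features by median absolute deviation
#'
#' Per feature, MAD = median(|x - median(x)|) over observed values (no
#' constant, no imputation). Returns the `ceiling(top_fraction * n)` features
#' with the largest MAD; ties broken by feature order, so selection is
#' deterministic.
#'
#' @param m a `SiteMatrix` or matrix (log2 scale recommended; MAD is
#'   shift-invariant per feature, so a shared multiplicative factor applied
#'   before log transform does not change the selection).
#' @param top_fraction fraction of features to keep, in (0, 1].
#' @return Object of the same kind restricted to the selected features, in
#'   original feature order.
#' @export
select_most_variable_mad <- function(m, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  mat <- as_feature_matrix(m)
  if (nrow(mat) < 1L) stop("no features to rank")
  mads <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(-Inf)
    median(abs(x - median(x)))
  })
  n_keep <- ceiling(top_fraction * nrow(mat))
  ord <- order(-mads, seq_along(mads))  # ties -> earlier feature wins
  keep <- sort(ord[seq_len(n_keep)])
  rewrap(m, mat[keep, , drop = FALSE], seq_len(nrow(mat)) %in% keep)
}

#' Log2 transform of observed intensities
#'
#' Applied before variance ranking, clustering and differential testing;
#' missing values are preserved.
#'
#' @param m a `SiteMatrix` or matrix of non-negative values.
#' @return Same kind, log2 on observed values.
#' @export
log2_prepare <- function(m) {
  mat <- as_feature_matrix(m)
  if (any(mat < 0, na.rm = TRUE)) stop("negative values cannot be logged")
  mat[!is.na(mat) & mat == 0] <- NA_real_
  rewrap(m, log2(mat))
}

#' Cohort-level quality report
#'
#' Per-sample site-identification counts, their Spearman correlation with
#' tumor cellularity, and sample-sample Pearson correlation on the
#' complete-data (100% DP) subset.
#'
#' @param m a `SiteMatrix`.
#' @param clinical clinical table with `sample_id` and `cellularity_pct`.
#' @return List with `id_counts`, `spearman_rho`, `spearman_p` (both `NA`
#'   when either vector is constant), and `sample_cor` (Pearson matrix on
#'   complete features, log2 scale).
#' @export
qc_correlations <- function(m, clinical) {
  stopifnot(inherits(m, "SiteMatrix"))
  if (ncol(m$intensity) < 3L) stop("need at least 3 samples")
  counts <- colSums(!is.na(m$intensity))
  cell <- clinical$cellularity_pct[match(samples_of(m), clinical$sample_id)]
  if (sd(counts) == 0 || sd(cell, na.rm = TRUE) == 0) {
    rho <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(counts, cell, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); pv <- ct$p.value
  }
  complete <- m$intensity[rowSums(is.na(m$intensity)) == 0L, , drop = FALSE]
  sc <- if (nrow(complete) >= 2L)
    suppressWarnings(cor(log2(complete))) else NULL
  list(id_counts = counts, spearman_rho = rho, spearman_p = pv,
       sample_cor = sc)
}
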