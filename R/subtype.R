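#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering for subtype discovery. For each
#' candidate k and each resample, a fraction of samples is drawn without
#' replacement and clustered on z-scored features (average-linkage
#' hierarchical by default); the consensus matrix entry M_k(i, j) is the
#' fraction of co-samplings of i and j in which they co-clustered. The
#' number of clusters is chosen from the relative increase of the area under
#' the empirical CDF of consensus entries: k grows while the relative gain
#' stays at or above `delta_min`. The default threshold (0.10) sits well
#' above the irreducible churn floor of roughly 2/n (the area gain produced
#' by re-assigning a single sample) and well below the gain from resolving a
#' genuine cluster, which exceeds 0.4 at desk-scale cohort sizes.
#'
#' Features still missing after upstream DP filtering are filled, inside
#' this function only, with the feature's observed minimum (a low-abundance
#' fill); distance computation requires complete vectors and the fill is
#' never persisted.
#'
#' @param m feature-by-sample matrix (log2 scale; typically the DP-filtered,
#'   MAD-selected matrix) or a `SiteMatrix`.
#' @param k_range candidate cluster counts, within `[2, n/2]`.
#' @param n_resamples resampling iterations per k (default 250).
#' @param subsample_fraction fraction of samples drawn per resample.
#' @param seed integer seed; identical seed gives identical results.
#' @param inner inner clustering algorithm per resample: `"hclust"`
#'   (average-linkage hierarchical on Euclidean distance, the default) or
#'   `"kmeans"`. The CDF-area k-selection rule relies on extra clusters
#'   being unstable when k exceeds the true structure; hierarchical cutting
#'   satisfies this (it peels small outlier groups), whereas k-means forces
#'   balanced splits that inflate the CDF area at every k, so k-means is
#'   offered for exploration but not used for k selection by default.
#' @param nstart k-means restarts per resample (inner = "kmeans").
#' @param delta_min threshold on the relative CDF-area increase used for k
#'   selection.
#' @param chosen_k optional override of the selected k.
#' @return An object of class `ConsensusResult`: `k_values`,
#'   `consensus` (list of n-by-n matrices), `cdf_area`, `delta_area`,
#'   `chosen_k`, `labels` (size-ranked cluster ids for `chosen_k`) and
#'   `labels_by_k`.
#' @export
consensus_cluster <- function(m, k_range = 2:6, n_resamples = 250L,
                              subsample_fraction = 0.8, seed = 1L,
                              inner = c("hclust", "kmeans"), nstart = 10L,
                              delta_min = 0.10, chosen_k = NULL) {
  inner <- match.arg(inner)
  mat <- as_feature_matrix(m)
  n <- ncol(mat)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > floor(n / 2))
    stop("k_range must lie within [2, n/2]")
  if (nrow(mat) < 2L) stop("need at least 2 features")
  samples <- colnames(mat) %||% paste0("S", seq_len(n))

  # low-abundance fill + per-feature z-score (constant features dropped)
  filled <- t(apply(mat, 1, function(x) {
    x[is.na(x)] <- min(x, na.rm = TRUE); x
  }))
  sds <- apply(filled, 1, sd)
  z <- (filled[sds > 0, , drop = FALSE] - rowMeans(
    filled[sds > 0, , drop = FALSE])) / sds[sds > 0]

  n_sub <- floor(subsample_fraction * n)
  idx_sets <- with_seed(stage_seed(seed, 0),
                        lapply(seq_len(n_resamples),
                               function(i) sort(sample(n, n_sub))))
  S <- matrix(0, n, n)
  for (idx in idx_sets) S[idx, idx] <- S[idx, idx] + 1
  if (any(S[upper.tri(S)] == 0))
    stop("some sample pairs were never co-sampled; increase n_resamples")

  consensus <- vector("list", length(k_range))
  names(consensus) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    I <- matrix(0, n, n)
    for (r in seq_len(n_resamples)) {
      idx <- idx_sets[[r]]
      sub <- t(z[, idx, drop = FALSE])
      cl <- if (inner == "kmeans") {
        with_seed(stage_seed(seed, ki * n_resamples + r),
                  kmeans(sub, centers = k, nstart = nstart,
                         iter.max = 50)$cluster)
      } else {
        cutree(hclust(dist(sub), method = "average"), k = k)
      }
      co <- outer(cl, cl, `==`) * 1
      I[idx, idx] <- I[idx, idx] + co
    }
    M <- I / S
    diag(M) <- 1
    dimnames(M) <- list(samples, samples)
    consensus[[ki]] <- M
  }

  areas <- vapply(consensus, cdf_area, numeric(1))
  delta <- numeric(length(areas))
  delta[1] <- areas[1]
  if (length(areas) > 1)
    delta[-1] <- diff(areas) / areas[-length(areas)]

  if (is.null(chosen_k)) {
    ok <- delta >= delta_min
    last <- if (all(ok)) length(k_range) else max(1L, which(!ok)[1] - 1L)
    chosen_k <- k_range[last]
  } else if (!chosen_k %in% k_range) {
    stop("chosen_k must be one of the computed k values")
  }

  labels_by_k <- lapply(seq_along(k_range), function(ki) {
    hc <- hclust(as.dist(1 - consensus[[ki]]), method = "average")
    setNames(cutree(hc, k = k_range[ki]), samples)
  })
  names(labels_by_k) <- as.character(k_range)

  res <- structure(list(k_values = k_range, consensus = consensus,
                        cdf_area = unname(areas), delta_area = unname(delta),
                        chosen_k = chosen_k, labels_by_k = labels_by_k),
                   class = "ConsensusResult")
  res$labels <- assign_labels(res, chosen_k)
  res
}

# area under the empirical CDF of off-diagonal consensus entries
cdf_area <- function(M) {
  x <- sort(M[upper.tri(M)])
  xs <- unique(x)
  if (length(xs) < 2L) return(0)
  cdf <- ecdf(x)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' Final cluster labels at a given k
#'
#' Labels come from average-linkage hierarchical clustering of
#' 1 - consensus, cut at k; cluster ids are renumbered by decreasing cluster
#' size (ties by first occurrence), so relabeling is deterministic.
#'
#' @param res a `ConsensusResult`.
#' @param k one of the computed k values.
#' @return Named integer vector of cluster labels.
#' @export
assign_labels <- function(res, k) {
  stopifnot(inherits(res, "ConsensusResult"))
  if (length(k) != 1L || !k %in% res$k_values)
    stop("k must be one of the computed k values: ",
         paste(res$k_values, collapse = ", "))
  raw <- res$labels_by_k[[as.character(k)]]
  sizes <- table(raw)
  new_order <- names(sort(sizes, decreasing = TRUE))
  map <- setNames(seq_along(new_order), new_order)
  setNames(as.integer(map[as.character(raw)]), names(raw))
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k in {%s}, chosen k = %d\n",
              paste(x$k_values, collapse = ", "), x$chosen_k))
  cat("  CDF areas:", paste(sprintf("%.3f", x$cdf_area), collapse = ", "),
      "\n")
  invisible(x)
}
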