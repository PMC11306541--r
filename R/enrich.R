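#' Single-sample rank enrichment score (ssGSEA convention)
#'
#' Keys are ranked by value, descending (ties broken by input order). The
#' score is the integrated difference between the weighted in-set ECDF
#' (weights |value|^alpha, normalized within the set) and the unweighted
#' out-of-set ECDF:
#' `ES = sum_i [ P_in(i) - P_out(i) ]`.
#' A set covering every key scores 0 by convention (its complement is
#' empty). If every value is equal the profile is uninformative and 0 is
#' returned with a tie warning.
#'
#' @param values named numeric vector (one unit: a sample's profile or a
#'   pre-ranked metric).
#' @param members character vector of set member keys.
#' @param alpha rank-weighting exponent (0.25 for intensity profiles; use 1
#'   with the signed -log10 p pre-ranked metric).
#' @return The enrichment score (scalar).
#' @export
ssgsea_score <- function(values, members, alpha = 0.25) {
  if (length(values) < 2L) stop("need at least 2 keys")
  if (is.null(names(values))) stop("values must be named by key")
  values <- values[!is.na(values)]
  N <- length(values)
  inset <- names(values) %in% members
  m <- sum(inset)
  if (m == 0L) return(NA_real_)           # empty intersection: skipped
  if (m == N) return(0)
  if (length(unique(values)) == 1L) {
    warning("all ranking values equal; enrichment score is 0")
    return(0)
  }
  ord <- order(-values)                   # stable: ties keep input order
  inset <- inset[ord]
  w <- abs(values[ord])^alpha * inset
  tot <- sum(w)
  p_in <- if (tot > 0) cumsum(w) / tot else cumsum(inset) / m
  p_out <- cumsum(!inset) / (N - m)
  sum(p_in - p_out)
}

#' Score a signature collection over every sample
#'
#' Applies [ssgsea_score()] per sample, using each sample's observed keys
#' only. Signatures whose intersection with the available keys falls outside
#' `[min_size, max_size]` are skipped for that sample (NA).
#'
#' @param mat key-by-sample numeric matrix (`NA` = missing).
#' @param sigs named list of member-key vectors (e.g. from [read_gmt()]).
#' @param alpha rank-weighting exponent.
#' @param min_size,max_size signature size bounds applied after intersecting
#'   with the observed keys (defaults 5 and 1000).
#' @return Signature-by-sample `ES` matrix wrapped in a list of class
#'   `EnrichmentResult` (elements `ES`, `alpha`, `skipped`).
#' @export
ssgsea_matrix <- function(mat, sigs, alpha = 0.25, min_size = 5L,
                          max_size = 1000L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ES <- matrix(NA_real_, length(sigs), ncol(mat),
               dimnames = list(names(sigs), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    v <- v[!is.na(v)]
    for (i in seq_along(sigs)) {
      sz <- sum(names(v) %in% sigs[[i]])
      if (sz < min_size || sz > max_size) next
      ES[i, j] <- ssgsea_score(v, sigs[[i]], alpha)
    }
  }
  structure(list(ES = ES, alpha = alpha, skipped = is.na(ES)),
            class = "EnrichmentResult")
}

#' Site-signature enrichment keyed by flanking windows (PTM-SEA style)
#'
#' Scores phosphosite signatures whose members are 15-mer flanking sequence
#' windows against the normalized site intensities. Duplicate windows are
#' collapsed first, keeping the most abundant entry by row-sum intensity.
#'
#' @param m a `SiteMatrix` (normalized intensities).
#' @param site_sigs named list of window vectors (15-mers, 'X'-padded).
#' @param alpha,min_size,max_size as in [ssgsea_matrix()].
#' @return An `EnrichmentResult`.
#' @export
ptm_sea_score <- function(m, site_sigs, alpha = 0.25, min_size = 5L,
                          max_size = 1000L) {
  stopifnot(inherits(m, "SiteMatrix"))
  if (any(nchar(m$annot$window) != 15L))
    stop("flanking windows must be 15-mers")
  bad <- unlist(lapply(site_sigs, function(s) s[nchar(s) != 15L]))
  if (length(bad))
    stop("signature window(s) not 15-mers: ", paste(head(bad, 3),
                                                    collapse = ", "))
  dd <- dedup_windows(m)
  ssgsea_matrix(dd$intensity, site_sigs, alpha, min_size, max_size)
}

# collapse duplicate flanking windows, keeping the max row-sum entry
dedup_windows <- function(m) {
  rs <- rowSums(m$intensity, na.rm = TRUE)
  ord <- order(-rs, seq_along(rs))     # highest abundance first, stable
  first <- ord[!duplicated(m$annot$window[ord])]
  keep <- sort(first)
  out <- subset_sites(m, seq_len(nrow(m$annot)) %in% keep)
  rownames(out$intensity) <- out$annot$window
  out
}

#' Average enrichment scores per cluster
#'
#' Arithmetic mean of member samples' scores, per signature.
#'
#' @param res an `EnrichmentResult` (or a plain ES matrix).
#' @param labels named cluster labels covering every scored sample.
#' @return Signature-by-cluster matrix of mean ES.
#' @export
average_by_cluster <- function(res, labels) {
  ES <- if (inherits(res, "EnrichmentResult")) res$ES else res
  miss <- setdiff(colnames(ES), names(labels))
  if (length(miss))
    stop("unlabeled sample(s): ", paste(miss, collapse = ", "))
  labs <- labels[colnames(ES)]
  cl <- sort(unique(labs))
  out <- vapply(cl, function(g)
    rowMeans(ES[, labs == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(ES)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(ES))
  dimnames(out) <- list(rownames(ES), as.character(cl))
  out
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d signatures x %d units (%d scores skipped)\n",
              nrow(x$ES), ncol(x$ES), sum(x$skipped)))
  invisible(x)
}
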