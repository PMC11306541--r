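#' Map peptide-level spectral counts onto phosphosites
#'
#' Each peptide contributes its per-sample MS/MS counts to every
#' (protein, position) site it carries; site-level counts are the sums over
#' covering peptides. Sites quantified in the site table but absent from the
#' evidence get 0.
#'
#' @param ev a `PeptideEvidence`.
#' @param m a `SiteMatrix` (defines the site universe and sample set).
#' @return Integer matrix site-key (`protein:position`) by sample.
#' @export
site_spectral_counts <- function(ev, m) {
  stopifnot(inherits(ev, "PeptideEvidence"), inherits(m, "SiteMatrix"))
  keys <- unique(site_key(m$annot))
  samples <- samples_of(m)
  out <- matrix(0L, length(keys), length(samples),
                dimnames = list(keys, samples))
  common <- intersect(colnames(ev$counts), samples)
  prot_l <- strsplit(ev$peptides$proteins, ";", fixed = TRUE)
  pos_l <- strsplit(ev$peptides$positions, ";", fixed = TRUE)
  for (i in seq_len(nrow(ev$counts))) {
    pk <- paste(prot_l[[i]], pos_l[[i]], sep = ":")
    pk <- pk[pk %in% keys]
    if (!length(pk)) next
    out[pk, common] <- out[pk, common] +
      matrix(rep(ev$counts[i, common], each = length(pk)), nrow = length(pk))
  }
  out
}

#' Build the four INKA evidence arms for one analysis unit
#'
#' Kinase-centric evidence: `c_kin` sums counts over the kinase's own
#' phosphosites excluding activation-loop sites, `c_act` sums the
#' activation-loop sites (so the two never double count). Substrate-centric
#' evidence: `c_psp` sums counts over sites with a curated edge from the
#' kinase; `c_nwk` sums sites with a predicted edge scoring at least
#' `nwk_min_score` *and* no curated edge from the same kinase (each site
#' counted once, curated arm wins).
#'
#' @param counts site-key-by-sample count matrix from
#'   [site_spectral_counts()] (or an intensity matrix if intensity-based
#'   evidence is preferred).
#' @param net a `KinaseSubstrateNetwork`.
#' @param unit character vector of sample names forming the unit (a single
#'   sample or a group); evidence is summed across the unit's samples.
#' @param nwk_min_score minimum prediction score for predicted edges
#'   (default 2, boundary inclusive).
#' @return data.frame with columns `kinase`, `c_kin`, `c_act`, `c_psp`,
#'   `c_nwk`.
#' @export
build_evidence_arms <- function(counts, net, unit = colnames(counts),
                                nwk_min_score = 2.0) {
  stopifnot(inherits(net, "KinaseSubstrateNetwork"))
  miss <- setdiff(unit, colnames(counts))
  if (length(miss))
    stop("unknown sample(s) in unit: ", paste(miss, collapse = ", "))
  v <- rowSums(counts[, unit, drop = FALSE])
  kin <- network_kinases(net)
  getv <- function(keys) sum(v[intersect(keys, names(v))])
  self_keys <- paste(net$self_sites$protein, net$self_sites$position,
                     sep = ":")
  edge_keys <- paste(net$edges$substrate, net$edges$position, sep = ":")
  arms <- lapply(kin, function(k) {
    own <- net$self_sites$kinase == k
    c_kin <- getv(self_keys[own & !net$self_sites$activation_loop])
    c_act <- getv(self_keys[own & net$self_sites$activation_loop])
    ek <- net$edges$kinase == k
    cur <- ek & net$edges$source == "curated"
    pred <- ek & net$edges$source == "predicted" &
      !is.na(net$edges$score) & net$edges$score >= nwk_min_score
    cur_keys <- edge_keys[cur]
    c_psp <- getv(cur_keys)
    c_nwk <- getv(setdiff(edge_keys[pred], cur_keys))
    data.frame(kinase = k, c_kin = c_kin, c_act = c_act, c_psp = c_psp,
               c_nwk = c_nwk, stringsAsFactors = FALSE)
  })
  do.call(rbind, arms)
}

#' Integrate evidence arms into an INKA profile
#'
#' Kinase-centric evidence K = c_kin + c_act; substrate-centric evidence
#' S = c_psp + c_nwk; the integrated activity score is their geometric mean
#' `sqrt(K * S)`, so a kinase needs both arms to score. Kinases with K > 0
#' but no substrate relations contributing evidence (S = 0) are excluded
#' from the ranked profile and reported separately as kinase-centric-only.
#' Ranks are assigned by decreasing score, ties broken alphabetically.
#'
#' @param arms output of [build_evidence_arms()].
#' @param unit,channel annotation carried on the profile.
#' @return data.frame of class `InkaProfile` (ranked, scored kinases) with
#'   attribute `"kinase_centric_only"`.
#' @export
inka_score <- function(arms, unit = "unit", channel = "pST") {
  K <- arms$c_kin + arms$c_act
  S <- arms$c_psp + arms$c_nwk
  score <- sqrt(K * S)
  kc_only <- arms$kinase[K > 0 & S == 0]
  keep <- !(K > 0 & S == 0)
  prof <- data.frame(kinase = arms$kinase, c_kin = arms$c_kin,
                     c_act = arms$c_act, c_psp = arms$c_psp,
                     c_nwk = arms$c_nwk, kin_evidence = K,
                     sub_evidence = S, score = score,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ord <- order(-prof$score, prof$kinase)
  prof <- prof[ord, , drop = FALSE]
  prof$rank <- seq_len(nrow(prof))
  rownames(prof) <- NULL
  attr(prof, "kinase_centric_only") <- kc_only
  attr(prof, "unit") <- unit
  attr(prof, "channel") <- channel
  class(prof) <- c("InkaProfile", "data.frame")
  prof
}

#' Per-sample INKA profiles
#'
#' @param counts site-key-by-sample count matrix.
#' @param net a `KinaseSubstrateNetwork`.
#' @param nwk_min_score predicted-edge score cutoff.
#' @param channel annotation.
#' @return Named list of `InkaProfile`s, one per sample.
#' @export
inka_sample_profiles <- function(counts, net, nwk_min_score = 2.0,
                                 channel = "pST") {
  setNames(lapply(colnames(counts), function(s)
    inka_score(build_evidence_arms(counts, net, s, nwk_min_score),
               unit = s, channel = channel)),
    colnames(counts))
}

#' Kinase-by-sample INKA score matrix
#'
#' Ranked kinases carry their scores; kinases evaluated in a unit but listed
#' kinase-centric-only (substrate evidence zero) carry 0, consistent with
#' the score being 0 whenever either evidence arm is 0. `NA` marks kinases
#' never evaluated for a unit.
#'
#' @param profiles list from [inka_sample_profiles()].
#' @return Numeric matrix kinase x sample.
#' @export
inka_score_matrix <- function(profiles) {
  kin <- sort(unique(unlist(lapply(profiles, function(p)
    c(p$kinase, attr(p, "kinase_centric_only"))))))
  out <- matrix(NA_real_, length(kin), length(profiles),
                dimnames = list(kin, names(profiles)))
  for (s in names(profiles)) {
    out[attr(profiles[[s]], "kinase_centric_only"), s] <- 0
    out[profiles[[s]]$kinase, s] <- profiles[[s]]$score
  }
  out
}

#' Group-based INKA profiles
#'
#' Evidence is pooled (summed, not averaged) across the group's samples
#' before arm construction, so rare but strong evidence is retained; the
#' per-kinase data presence (DP%, the percentage of the group's samples
#' whose individual score is positive) exposes that sparsity.
#'
#' @param counts site-key-by-sample count matrix.
#' @param net a `KinaseSubstrateNetwork`.
#' @param labels named group labels covering the samples in `counts`.
#' @param nwk_min_score predicted-edge score cutoff.
#' @param channel annotation.
#' @return Named list of `InkaProfile`s (one per group) carrying a `dp_pct`
#'   column.
#' @export
group_profile <- function(counts, net, labels, nwk_min_score = 2.0,
                          channel = "pST") {
  labs <- labels[colnames(counts)]
  if (any(is.na(labs))) stop("every sample needs a group label")
  per_sample <- inka_sample_profiles(counts, net, nwk_min_score, channel)
  smat <- inka_score_matrix(per_sample)
  groups <- sort(unique(labs))
  setNames(lapply(groups, function(gr) {
    members <- colnames(counts)[labs == gr]
    if (!length(members)) stop("empty group: ", gr)
    prof <- inka_score(build_evidence_arms(counts, net, members,
                                           nwk_min_score),
                       unit = as.character(gr), channel = channel)
    sm <- smat[, members, drop = FALSE]
    pos <- rowMeans(!is.na(sm) & sm > 0)
    prof$dp_pct <- round(100 * unname(pos[prof$kinase]))
    prof
  }), as.character(groups))
}

#' Top-n slice of an INKA profile
#'
#' @param profile an `InkaProfile`.
#' @param n number of top-ranked kinases (default 20). If fewer kinases are
#'   scored, all are returned with a note attribute.
#' @return The first `n` rows by rank.
#' @export
top_n <- function(profile, n = 20L) {
  stopifnot(inherits(profile, "InkaProfile"))
  if (n >= nrow(profile)) {
    out <- profile
    attr(out, "note") <- sprintf("only %d kinases scored", nrow(profile))
    return(out)
  }
  profile[seq_len(n), , drop = FALSE]
}

#' Differential kinase activity between groups
#'
#' Mann-Whitney test on per-sample INKA scores per kinase across two groups,
#' with BH adjustment. Kinases scored in fewer than 2 samples of either
#' group, or zero throughout, are skipped.
#'
#' @param smat kinase-by-sample score matrix ([inka_score_matrix()]).
#' @param labels named two-level group labels.
#' @return data.frame with `kinase`, medians per group, `p`, `q`,
#'   `higher_in`.
#' @export
compare_profiles <- function(smat, labels) {
  labs <- factor(labels[colnames(smat)])
  if (nlevels(labs) != 2L) stop("compare_profiles expects exactly 2 groups")
  lev <- levels(labs)
  rows <- lapply(rownames(smat), function(k) {
    x <- smat[k, labs == lev[1]]
    y <- smat[k, labs == lev[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L || (all(x == 0) && all(y == 0)))
      return(NULL)
    nt <- nonparametric_tests(c(x, y), rep(lev, c(length(x), length(y))))
    data.frame(kinase = k, median_1 = median(x), median_2 = median(y),
               p = nt$p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(NULL)
  names(rows)[2:3] <- paste0("median_", lev)
  rows$q <- bh_adjust(pmax(rows$p, .Machine$double.xmin))
  rows$higher_in <- ifelse(rows[[2]] >= rows[[3]], lev[1], lev[2])
  rows[order(rows$p), , drop = FALSE]
}

#' @export
print.InkaProfile <- function(x, ...) {
  cat(sprintf("InkaProfile [%s, unit %s]: %d kinases ranked",
              attr(x, "channel"), attr(x, "unit"), nrow(x)))
  kc <- attr(x, "kinase_centric_only")
  if (length(kc)) cat(sprintf(" (+%d kinase-centric-only)", length(kc)))
  cat("\n")
  print.data.frame(head(x, 10))
  invisible(x)
}
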