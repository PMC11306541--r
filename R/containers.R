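#' Phosphosite quantification matrix
#'
#' A `SiteMatrix` couples per-site annotation (identity, flanking sequence
#' window, localization probability, decoy/contaminant flags) with a
#' site-by-sample intensity matrix. Missing observations are stored as `NA`;
#' MaxQuant writes 0 for unobserved intensities and both are treated as
#' "not observed".
#'
#' @param annot data.frame with columns `protein`, `gene`, `position`,
#'   `residue`, `window`, `loc_prob`, `multiplicity`, `reverse`,
#'   `contaminant`. One row per phosphosite record.
#' @param intensity numeric matrix, rows matching `annot` rows (rownames are
#'   site ids `protein_position_multiplicity`), columns are samples. `NA`
#'   encodes a missing observation.
#' @param channel either `"global_pST"` (IMAC serine/threonine channel) or
#'   `"pY"` (phosphotyrosine immunoprecipitation channel).
#' @return An object of class `SiteMatrix`.
#' @export
site_matrix <- function(annot, intensity, channel = c("global_pST", "pY")) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(annot), is.matrix(intensity),
            nrow(annot) == nrow(intensity))
  needed <- c("protein", "gene", "position", "residue", "window",
              "loc_prob", "multiplicity", "reverse", "contaminant")
  miss <- setdiff(needed, names(annot))
  if (length(miss))
    stop("site annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (any(annot$position < 1))
    stop("site positions must be 1-based (>= 1)")
  if (any(annot$loc_prob < 0 | annot$loc_prob > 1, na.rm = TRUE))
    stop("localization probabilities must lie in [0, 1]")
  bad_centre <- nchar(annot$window) == 15L &
    substr(annot$window, 8L, 8L) != annot$residue
  if (any(bad_centre))
    stop("flank window centre does not match residue for ",
         sum(bad_centre), " record(s)")
  ids <- site_id(annot)
  if (anyDuplicated(ids))
    stop("duplicate (protein, position, multiplicity) keys in channel ",
         channel)
  rownames(intensity) <- ids
  structure(list(annot = annot, intensity = intensity, channel = channel),
            class = "SiteMatrix")
}

site_id <- function(annot) {
  paste(annot$protein, annot$position, annot$multiplicity, sep = "_")
}

# protein:position key used to join sites against the kinase-substrate network
site_key <- function(annot) paste(annot$protein, annot$position, sep = ":")

#' @export
print.SiteMatrix <- function(x, ...) {
  cat(sprintf("SiteMatrix [%s]: %d sites x %d samples (%.1f%% observed)\n",
              x$channel, nrow(x$intensity), ncol(x$intensity),
              100 * mean(!is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.SiteMatrix <- function(x) dim(x$intensity)

samples_of <- function(m) colnames(m$intensity)

subset_sites <- function(m, keep) {
  m$annot <- m$annot[keep, , drop = FALSE]
  m$intensity <- m$intensity[keep, , drop = FALSE]
  m
}

#' Peptide-level spectral-count evidence
#'
#' Aggregated MS/MS identification counts per modified peptide and sample,
#' with the protein accessions and 1-based site positions each peptide
#' carries, as derived from a MaxQuant evidence table.
#'
#' @param peptides data.frame with columns `modified_sequence`, `proteins`
#'   (";"-separated accessions) and `positions` (";"-separated 1-based
#'   residue indices, parallel to `proteins`).
#' @param counts integer matrix of summed MS/MS counts, peptides x samples;
#'   0 where a peptide was not observed.
#' @param intensity optional numeric matrix of peptide intensities.
#' @return An object of class `PeptideEvidence`.
#' @export
peptide_evidence <- function(peptides, counts, intensity = NULL) {
  stopifnot(is.data.frame(peptides), nrow(peptides) == nrow(counts))
  if (any(counts < 0)) stop("spectral counts must be non-negative")
  if (any(counts != round(counts))) stop("spectral counts must be integers")
  rownames(counts) <- peptides$modified_sequence
  structure(list(peptides = peptides, counts = counts, intensity = intensity),
            class = "PeptideEvidence")
}

#' @export
print.PeptideEvidence <- function(x, ...) {
  cat(sprintf("PeptideEvidence: %d peptides x %d samples, %d MS/MS total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Directed kinase-substrate relation set
#'
#' Substrate edges (curated or predicted, the latter scored), kinase
#' self-sites and flagged activation-loop sites; the evidence backbone for
#' INKA scoring.
#'
#' @param edges data.frame with columns `kinase`, `substrate`, `position`,
#'   `residue`, `source` (`"curated"` or `"predicted"`), `score` (`NA` for
#'   curated edges, required for predicted ones).
#' @param self_sites data.frame with columns `kinase`, `protein`, `position`,
#'   `residue`, `activation_loop` (logical; exactly one `TRUE` row per
#'   kinase).
#' @return An object of class `KinaseSubstrateNetwork`.
#' @export
kinase_network <- function(edges, self_sites) {
  stopifnot(is.data.frame(edges), is.data.frame(self_sites))
  if (!all(edges$source %in% c("curated", "predicted")))
    stop("edge source must be 'curated' or 'predicted'")
  pred <- edges$source == "predicted"
  if (any(pred & !is.finite(edges$score)))
    stop("predicted edges must carry a finite prediction score")
  key <- paste(edges$kinase, edges$substrate, edges$position, edges$source)
  if (anyDuplicated(key))
    stop("duplicate (kinase, substrate, position) pair within a source")
  structure(list(edges = edges, self_sites = self_sites),
            class = "KinaseSubstrateNetwork")
}

#' @export
print.KinaseSubstrateNetwork <- function(x, ...) {
  cat(sprintf(
    "KinaseSubstrateNetwork: %d kinases, %d edges (%d curated, %d predicted)\n",
    length(unique(x$self_sites$kinase)), nrow(x$edges),
    sum(x$edges$source == "curated"), sum(x$edges$source == "predicted")))
  invisible(x)
}

network_kinases <- function(net) sort(unique(net$self_sites$kinase))

validate_clinical <- function(cl) {
  needed <- c("sample_id", "os_months", "event_flag", "treatment_naive",
              "cellularity_pct", "kras_status", "tp53_status")
  miss <- setdiff(needed, names(cl))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(cl$os_months <= 0))
    stop("clinical validation: os_months must be > 0 (row ",
         which(cl$os_months <= 0)[1], ")")
  for (fl in c("event_flag", "treatment_naive"))
    if (!all(cl[[fl]] %in% c(0, 1)))
      stop("clinical validation: ", fl, " must be 0/1")
  if (any(cl$cellularity_pct < 0 | cl$cellularity_pct > 100))
    stop("clinical validation: cellularity_pct must be in [0, 100]")
  cl
}
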