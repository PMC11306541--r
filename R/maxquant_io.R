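#' Read a MaxQuant "Phospho (STY) Sites"-dialect table
#'
#' Parses the tab-separated site table into a [site_matrix()]. Sample names
#' are taken verbatim from the suffixes of the "Intensity <sample>" columns.
#' Intensities written as 0 or left empty are stored as missing (`NA`):
#' MaxQuant writes 0 for unobserved sites, so zero and absent are both
#' treated as "not observed".
#'
#' @param path TSV path.
#' @param channel `"global_pST"` or `"pY"`.
#' @return A `SiteMatrix`.
#' @export
read_sites <- function(path, channel = c("global_pST", "pY")) {
  channel <- match.arg(channel)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Protein", "Position", "Amino acid", "Localization prob",
                "Sequence window", "Reverse", "Potential contaminant")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("format error: missing required header(s): ",
         paste(miss, collapse = ", "))
  int_cols <- grep("^Intensity ", names(tab), value = TRUE)
  if (!length(int_cols))
    stop("format error: no 'Intensity <sample>' columns found")
  samples <- sub("^Intensity ", "", int_cols)
  int <- matrix(NA_real_, nrow(tab), length(int_cols),
                dimnames = list(NULL, samples))
  for (j in seq_along(int_cols)) {
    raw <- tab[[int_cols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | trimws(as.character(raw)) == ""))
    if (length(bad))
      stop("parse error: non-numeric intensity in column '", int_cols[j],
           "', row ", bad[1])
    int[, j] <- val
  }
  int[!is.na(int) & int == 0] <- NA_real_
  annot <- data.frame(
    protein = as.character(tab$Protein),
    gene = as.character(tab[["Gene names"]] %||% rep("", nrow(tab))),
    position = as.integer(tab$Position),
    residue = as.character(tab[["Amino acid"]]),
    window = as.character(tab[["Sequence window"]]),
    loc_prob = as.numeric(tab[["Localization prob"]]),
    multiplicity = as.integer(tab$Multiplicity %||% rep(1L, nrow(tab))),
    reverse = as.character(tab$Reverse) %in% "+",
    contaminant = as.character(tab[["Potential contaminant"]]) %in% "+",
    stringsAsFactors = FALSE)
  site_matrix(annot, int, channel)
}

#' Exclude decoy, contaminant and signal-free site records
#'
#' Removes reverse-database hits, potential contaminants, and rows whose
#' intensity is absent (or zero) in every sample. The counts removed per
#' reason are attached as attribute `"removed"`.
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @param m a `SiteMatrix`.
#' @return The filtered `SiteMatrix`.
#' @export
exclude_records <- function(m) {
  stopifnot(inherits(m, "SiteMatrix"))
  rev <- m$annot$reverse
  con <- m$annot$contaminant
  empty <- rowSums(!is.na(m$intensity)) == 0L
  keep <- !(rev | con | empty)
  out <- subset_sites(m, keep)
  attr(out, "removed") <- c(reverse = sum(rev), contaminant = sum(con & !rev),
                            all_missing = sum(empty & !rev & !con))
  out
}

#' Retain class-I localized phosphosites
#'
#' Keeps records whose localization probability is at least `threshold`
#' (inclusive; the class-I convention is >= 0.75).
#'
#' @param m a `SiteMatrix`.
#' @param threshold localization probability cutoff in (0, 1].
#' @return The filtered `SiteMatrix`.
#' @export
filter_class1 <- function(m, threshold = 0.75) {
  stopifnot(inherits(m, "SiteMatrix"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  subset_sites(m, m$annot$loc_prob >= threshold)
}

#' Aggregate MS/MS spectral counts from a MaxQuant evidence table
#'
#' Sums "MS/MS count" over all evidence rows of each (modified peptide,
#' sample) pair; peptides unobserved in a sample get 0.
#'
#' @param path evidence TSV with "Modified sequence", "Experiment" and
#'   "MS/MS count" columns (optionally "Proteins", "Positions within
#'   proteins", "Intensity").
#' @return A `PeptideEvidence`.
#' @export
spectral_counts_from_evidence <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Modified sequence", "Experiment", "MS/MS count")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("format error: missing required header(s): ",
         paste(miss, collapse = ", "))
  ct <- as.numeric(tab[["MS/MS count"]])
  if (any(!is.finite(ct)) || any(ct < 0))
    stop("format error: MS/MS counts must be non-negative numbers")
  peps <- sort(unique(tab[["Modified sequence"]]))
  samp <- sort(unique(tab$Experiment))
  counts <- matrix(0L, length(peps), length(samp),
                   dimnames = list(peps, samp))
  agg <- tapply(ct, list(tab[["Modified sequence"]], tab$Experiment), sum)
  counts[!is.na(agg)] <- as.integer(agg[!is.na(agg)])
  first <- !duplicated(tab[["Modified sequence"]])
  meta <- tab[first, , drop = FALSE]
  meta <- meta[match(peps, meta[["Modified sequence"]]), , drop = FALSE]
  peptides <- data.frame(
    modified_sequence = peps,
    proteins = as.character(meta$Proteins %||% rep("", length(peps))),
    positions = as.character(meta[["Positions within proteins"]] %||%
                               rep("", length(peps))),
    stringsAsFactors = FALSE)
  inten <- NULL
  if ("Intensity" %in% names(tab)) {
    ia <- tapply(as.numeric(tab$Intensity),
                 list(tab[["Modified sequence"]], tab$Experiment), sum)
    inten <- matrix(0, length(peps), length(samp),
                    dimnames = list(peps, samp))
    inten[!is.na(ia)] <- ia[!is.na(ia)]
  }
  peptide_evidence(peptides, counts, inten)
}

#' Read a kinase-substrate network table
#'
#' The TSV has columns kinase, substrate, position, residue, source, score.
#' Source is one of `curated`, `predicted` (substrate edges; predicted rows
#' must carry a numeric score), `self` or `activation_loop` (the kinase's own
#' sites).
#'
#' @param path network TSV.
#' @return A `KinaseSubstrateNetwork`.
#' @export
read_network <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("kinase", "substrate", "position", "residue", "source")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("format error: missing required header(s): ",
         paste(miss, collapse = ", "))
  ok_src <- c("curated", "predicted", "self", "activation_loop")
  bad <- which(!tab$source %in% ok_src)
  if (length(bad))
    stop("format error: unknown source '", tab$source[bad[1]],
         "' at line ", bad[1] + 1L)
  score <- suppressWarnings(as.numeric(tab$score %||% rep(NA, nrow(tab))))
  bad <- which(tab$source == "predicted" & !is.finite(score))
  if (length(bad))
    stop("format error: predicted edge without numeric score at line ",
         bad[1] + 1L)
  is_edge <- tab$source %in% c("curated", "predicted")
  edges <- data.frame(kinase = tab$kinase[is_edge],
                      substrate = tab$substrate[is_edge],
                      position = as.integer(tab$position[is_edge]),
                      residue = tab$residue[is_edge],
                      source = tab$source[is_edge],
                      score = score[is_edge], stringsAsFactors = FALSE)
  own <- tab[!is_edge, , drop = FALSE]
  self_sites <- data.frame(kinase = own$kinase, protein = own$substrate,
                           position = as.integer(own$position),
                           residue = own$residue,
                           activation_loop = own$source == "activation_loop",
                           stringsAsFactors = FALSE)
  kinase_network(edges, self_sites)
}

#' Read gene- or site-set signatures in GMT dialect
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Sets
#' smaller than `min_size` are kept but flagged (attribute `"small"`);
#' enrichment scoring applies the size bounds.
#'
#' @param path GMT file.
#' @param min_size sets below this size are flagged.
#' @return Named list of unique member vectors, with a `description`
#'   attribute per set.
#' @export
read_gmt <- function(path, min_size = 5L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("format error: malformed GMT line ", i,
           " (need name, description, >=1 member)")
    nm[i] <- parts[1]
    s <- unique(parts[-(1:2)])
    attr(s, "description") <- parts[2]
    sets[[i]] <- s
  }
  names(sets) <- nm
  attr(sets, "small") <- nm[vapply(sets, length, 1L) < min_size]
  sets
}

#' Read and validate a clinical table
#'
#' @param path CSV with columns sample_id, os_months, event_flag,
#'   treatment_naive, cellularity_pct, kras_status, tp53_status (mutation
#'   columns may carry allele strings alongside).
#' @return Validated data.frame.
#' @export
read_clinical <- function(path) {
  validate_clinical(read.csv(path, stringsAsFactors = FALSE))
}
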