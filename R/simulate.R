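#' Simulation configuration for a synthetic phosphoproteomic cohort
#'
#' Defines the study conditions of the generated cohort: cohort size and
#' subtype structure, the kinase-substrate network dimensions, the
#' log2-intensity signal model, missing-not-at-random dropout, spectral-count
#' generation, clinical covariates and survival. Defaults emulate a resected
#' pancreatic adenocarcinoma cohort of 42 tumors profiled in two channels
#' (global pS/T IMAC for all samples; pY IP for a 33-sample subset).
#'
#' @param n_samples cohort size.
#' @param n_subtypes number of planted molecular subtypes (>= 2).
#' @param n_kinases number of kinases in the network.
#' @param n_sites_global,n_sites_py substrate-site universe per channel.
#' @param edges_per_kinase substrate edges drawn per kinase.
#' @param predicted_fraction fraction of edges tagged as predicted (scored)
#'   rather than curated.
#' @param activity_base baseline kinase activity on the log2-intensity scale.
#' @param activity_shift additive log2 activity gain a kinase receives in the
#'   samples of its assigned subtype.
#' @param hyper_kinase kinase receiving one extra `activity_shift` on top of
#'   its subtype shift, making it the uniquely hyperactive kinase of its
#'   subtype; also the default prognostic kinase.
#' @param noise_sd residual log2 SD of site intensities around the
#'   kinase-driven mean.
#' @param missing_gamma0,missing_gamma1 intercept and slope of the logistic
#'   observation model P(observed) = plogis(gamma0 + gamma1 * log2 intensity);
#'   positive slope makes low-intensity sites drop out more (MNAR).
#' @param count_scale,count_cap spectral counts are Poisson with mean
#'   `min(count_cap, count_scale * 2^(log2I - activity_base))`; the cap
#'   reflects the saturation of spectral counting in shotgun data.
#' @param loc_class1_fraction fraction of sites drawn with localization
#'   probability >= 0.75 (class I).
#' @param prognostic_kinase kinase whose standardized activity drives the
#'   survival hazard.
#' @param hazard_beta log-hazard increase per unit standardized activity of
#'   the prognostic kinase.
#' @param os_base_median median overall survival (months) at average
#'   prognostic activity.
#' @param censor_rate approximate marginal fraction of censored samples.
#' @param naive_fraction fraction of treatment-naive patients.
#' @param mut_freq_kras,mut_freq_tp53 mutation frequencies (defaults are the
#'   cohort frequencies 40/42 and 31/42).
#' @param py_channel_dropout fraction of samples lacking the pY channel
#'   (default 9/42).
#' @param seed integer seed; identical seed and config give byte-identical
#'   cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 42L, n_subtypes = 3L, n_kinases = 18L,
                       n_sites_global = 800L, n_sites_py = 150L,
                       edges_per_kinase = 12L, predicted_fraction = 0.35,
                       activity_base = 20, activity_shift = 3,
                       hyper_kinase = "KIN01", noise_sd = 0.8,
                       missing_gamma0 = -10, missing_gamma1 = 0.6,
                       count_scale = 1, count_cap = 50L,
                       loc_class1_fraction = 0.9,
                       prognostic_kinase = "KIN01", hazard_beta = 0.8,
                       os_base_median = 18, censor_rate = 0.25,
                       naive_fraction = 23 / 42,
                       mut_freq_kras = 0.952, mut_freq_tp53 = 0.738,
                       py_channel_dropout = 9 / 42, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("predicted_fraction", "loc_class1_fraction", "censor_rate",
          "naive_fraction", "mut_freq_kras", "mut_freq_tp53",
          "py_channel_dropout")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (cfg$n_subtypes < 2) stop("configuration error: n_subtypes must be >= 2")
  cnt <- c("n_samples", "n_kinases", "n_sites_global", "n_sites_py",
           "edges_per_kinase")
  for (f in cnt)
    if (cfg[[f]] <= 0) stop("configuration error: ", f, " must be > 0")
  if (cfg$noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

kinase_ids <- function(n) sprintf("KIN%02d", seq_len(n))

#' Simulate a kinase-substrate relation network
#'
#' Draws a bipartite kinase-to-substrate-site relation set. Each edge is
#' tagged curated or predicted (predicted edges carry a prediction score on a
#' NetworKIN-like 1-6 scale). Every kinase additionally owns one self-site on
#' its own protein (kinase-centric evidence) and exactly one flagged
#' activation-loop site. Residues are tyrosine for tyrosine kinases (every
#' third kinase) and S/T otherwise; substrate edges are drawn from the
#' matching channel's site pool.
#'
#' @param n_kinases,n_sites,edges_per_kinase network dimensions; sites are
#'   split between an S/T and a Y pool via `py_fraction`.
#' @param predicted_fraction fraction of edges tagged predicted.
#' @param seed integer seed.
#' @param py_fraction fraction of substrate sites that are tyrosines.
#' @return A list with the `KinaseSubstrateNetwork` (`$network`) and the
#'   substrate-site universe (`$sites`: data.frame with `protein`,
#'   `position`, `residue`, `window`).
#' @export
simulate_network <- function(n_kinases, n_sites, edges_per_kinase,
                             predicted_fraction = 0.35, seed = 1L,
                             py_fraction = 0) {
  if (edges_per_kinase > n_sites)
    stop("configuration error: edges_per_kinase exceeds n_sites")
  with_seed(seed, {
    kin <- kinase_ids(n_kinases)
    tyr <- rep_len(c(FALSE, FALSE, TRUE), n_kinases)  # every 3rd is a TK
    n_py <- round(py_fraction * n_sites)
    residue <- c(sample(c("S", "T"), n_sites - n_py, replace = TRUE,
                        prob = c(0.8, 0.2)),
                 rep("Y", n_py))
    sites <- data.frame(
      protein = sprintf("SUB%04d", ceiling(seq_len(n_sites) / 4)),
      position = integer(n_sites), residue = residue,
      stringsAsFactors = FALSE)
    # unique positions within each protein
    for (p in unique(sites$protein)) {
      i <- which(sites$protein == p)
      sites$position[i] <- sort(sample(5:995, length(i)))
    }
    sites$window <- random_window(sites$residue)

    pool_st <- which(sites$residue %in% c("S", "T"))
    pool_y <- which(sites$residue == "Y")
    edges <- vector("list", n_kinases)
    for (i in seq_len(n_kinases)) {
      pool <- if (tyr[i] && length(pool_y) >= edges_per_kinase) pool_y
              else pool_st
      tgt <- sample(pool, edges_per_kinase)
      pred <- runif(edges_per_kinase) < predicted_fraction
      edges[[i]] <- data.frame(
        kinase = kin[i],
        substrate = sites$protein[tgt], position = sites$position[tgt],
        residue = sites$residue[tgt],
        source = ifelse(pred, "predicted", "curated"),
        score = ifelse(pred, round(runif(edges_per_kinase, 1, 6), 2), NA),
        stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    res_self <- ifelse(tyr, "Y", "S")
    self_sites <- data.frame(
      kinase = rep(kin, each = 2L),
      protein = rep(paste0(kin, "P"), each = 2L),
      position = as.integer(rbind(101L + seq_len(n_kinases),
                                  301L + seq_len(n_kinases))),
      residue = rep(res_self, each = 2L),
      activation_loop = rep(c(FALSE, TRUE), n_kinases),
      stringsAsFactors = FALSE)
    list(network = kinase_network(edges, self_sites), sites = sites)
  })
}

random_window <- function(residue) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(residue, function(r) {
    fl <- sample(aa, 14, replace = TRUE)
    paste0(paste(fl[1:7], collapse = ""), r, paste(fl[8:14], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Generates the complete data bundle the pipeline consumes: a global pS/T
#' and a pY `SiteMatrix`, peptide-level spectral-count evidence, a clinical
#' table with survival, and the planted truth. The signal model: kinase
#' activity `a[k, s] = activity_base + activity_shift * [kinase assigned to
#' subtype(s)] + N(0, 1)` (the designated hyperactive kinase receives one
#' extra shift); site log2 intensity is the mean activity of its incoming
#' kinases plus `N(0, noise_sd)`; observation is Bernoulli-logistic in log2
#' intensity (MNAR); spectral counts are capped Poisson in linear intensity;
#' survival is exponential with log-hazard `hazard_beta` per unit
#' standardized prognostic-kinase activity, with independent exponential
#' censoring.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_cohort` with elements `truth` (labels,
#'   activities, network, counts, survival generator state), `sites_global`,
#'   `sites_py`, `evidence` (`PeptideEvidence` spanning both channels) and
#'   `clinical`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  net_sim <- simulate_network(
    cfg$n_kinases, cfg$n_sites_global + cfg$n_sites_py,
    cfg$edges_per_kinase, cfg$predicted_fraction,
    seed = stage_seed(cfg$seed, 1),
    py_fraction = cfg$n_sites_py / (cfg$n_sites_global + cfg$n_sites_py))
  net <- net_sim$network
  with_seed(stage_seed(cfg$seed, 2), {
    n <- cfg$n_samples
    samples <- sprintf("Sample%02d", seq_len(n))
    subtype <- sample(rep_len(seq_len(cfg$n_subtypes), n))
    names(subtype) <- samples
    kin <- kinase_ids(cfg$n_kinases)
    kin_subtype <- setNames(rep_len(seq_len(cfg$n_subtypes),
                                    cfg$n_kinases), kin)

    # kinase activity matrix (log2 scale)
    act <- matrix(rnorm(cfg$n_kinases * n), cfg$n_kinases, n,
                  dimnames = list(kin, samples))
    act <- act + cfg$activity_base
    for (k in kin) {
      in_sub <- subtype == kin_subtype[k]
      act[k, in_sub] <- act[k, in_sub] + cfg$activity_shift
      if (identical(k, cfg$hyper_kinase))
        act[k, in_sub] <- act[k, in_sub] + cfg$activity_shift
    }

    # site universe = substrate sites + kinase self/activation-loop sites
    all_sites <- rbind(
      net_sim$sites,
      data.frame(protein = net$self_sites$protein,
                 position = net$self_sites$position,
                 residue = net$self_sites$residue,
                 window = random_window(net$self_sites$residue),
                 stringsAsFactors = FALSE))
    keys <- paste(all_sites$protein, all_sites$position, sep = ":")
    # incoming kinases per site: substrate edges + self ownership
    inc <- split(net$edges$kinase,
                 paste(net$edges$substrate, net$edges$position, sep = ":"))
    self_key <- paste(net$self_sites$protein, net$self_sites$position,
                      sep = ":")
    for (i in seq_along(self_key))
      inc[[self_key[i]]] <- unique(c(inc[[self_key[i]]],
                                     net$self_sites$kinase[i]))

    n_sites <- nrow(all_sites)
    logI <- matrix(rnorm(n_sites * n, sd = cfg$noise_sd), n_sites, n,
                   dimnames = list(keys, samples))
    for (i in seq_len(n_sites)) {
      ks <- inc[[keys[i]]]
      drive <- if (is.null(ks)) cfg$activity_base
               else colMeans(act[ks, , drop = FALSE])
      logI[i, ] <- logI[i, ] + drive
    }

    observed <- matrix(
      rbinom(n_sites * n, 1L,
             plogis(cfg$missing_gamma0 + cfg$missing_gamma1 * logI)) == 1L,
      n_sites, n)
    lambda <- pmin(cfg$count_cap,
                   cfg$count_scale * 2^(logI - cfg$activity_base))
    counts <- matrix(rpois(n_sites * n, lambda), n_sites, n,
                     dimnames = dimnames(logI))
    counts[!observed] <- 0L
    intensity <- 2^logI
    intensity[!observed] <- NA_real_

    loc_prob <- ifelse(runif(n_sites) < cfg$loc_class1_fraction,
                       runif(n_sites, 0.75, 1), runif(n_sites, 0.05, 0.75))
    annot <- data.frame(
      protein = all_sites$protein,
      gene = sub("P$", "", paste0("g", all_sites$protein)),
      position = all_sites$position, residue = all_sites$residue,
      window = all_sites$window, loc_prob = round(loc_prob, 6),
      multiplicity = 1L, reverse = FALSE, contaminant = FALSE,
      stringsAsFactors = FALSE)

    is_y <- annot$residue == "Y"
    n_drop <- round(cfg$py_channel_dropout * n)
    py_samples <- if (n_drop > 0) samples[-sample(n, n_drop)] else samples
    sites_global <- site_matrix(annot[!is_y, , drop = FALSE],
                                intensity[!is_y, , drop = FALSE],
                                "global_pST")
    sites_py <- site_matrix(annot[is_y, , drop = FALSE],
                            intensity[is_y, py_samples, drop = FALSE], "pY")

    # survival: exponential PH in standardized prognostic activity
    a_prog <- act[cfg$prognostic_kinase, ]
    z <- as.numeric(scale(a_prog))
    rate0 <- log(2) / cfg$os_base_median
    t_event <- rexp(n, rate0 * exp(cfg$hazard_beta * z))
    cens_rate <- if (cfg$censor_rate > 0)
      rate0 * cfg$censor_rate / (1 - cfg$censor_rate) else 0
    t_cens <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
    os <- pmax(0.1, round(pmin(t_event, t_cens), 1))
    event <- as.integer(t_event <= t_cens)

    kras_mut <- rbinom(n, 1L, cfg$mut_freq_kras)
    alleles <- c("G12V", "G12D", "G12R", "G12R/G12V", "G13D", "Q61H", "")
    allele_p <- c(0.40, 0.35, 0.10, 0.025, 0.025, 0.025, 0.075)
    kras_allele <- ifelse(kras_mut == 1L,
                          sample(alleles, n, TRUE, allele_p), "WT")
    clinical <- data.frame(
      sample_id = samples, os_months = os, event_flag = event,
      treatment_naive = rbinom(n, 1L, cfg$naive_fraction),
      cellularity_pct = pmin(70, pmax(10, round(rnorm(n, 40, 15)))),
      kras_status = kras_mut, kras_allele = kras_allele,
      tp53_status = rbinom(n, 1L, cfg$mut_freq_tp53),
      stringsAsFactors = FALSE)
    validate_clinical(clinical)

    # one peptide per site; counts restricted to the channel's samples
    counts_ev <- counts
    if (n_drop > 0)
      counts_ev[is_y, setdiff(samples, py_samples)] <- 0L
    peptides <- data.frame(
      modified_sequence = paste0("_", annot$window, "(ph)_"),
      proteins = annot$protein, positions = as.character(annot$position),
      stringsAsFactors = FALSE)
    ev_int <- intensity
    ev_int[is.na(ev_int)] <- 0
    evidence <- peptide_evidence(peptides, counts_ev, ev_int)

    truth <- structure(list(
      subtype_labels = subtype, kinase_subtypes = kin_subtype,
      activities = act, network = net, site_keys = keys,
      log_intensity = logI, observed = observed,
      counts = counts_ev, prognostic_kinase = cfg$prognostic_kinase,
      hyper_kinase = cfg$hyper_kinase, py_samples = py_samples,
      config = cfg), class = "sim_truth")
    structure(list(truth = truth, sites_global = sites_global,
                   sites_py = sites_py, evidence = evidence,
                   clinical = clinical),
              class = "sim_cohort")
  })
}

#' Write a simulated cohort as MaxQuant-dialect fixture files
#'
#' Emits "Phospho (STY) Sites"-dialect TSVs per channel, a
#' modificationSpecificPeptides TSV, an evidence TSV (one or two rows per
#' observed peptide/sample whose MS/MS counts sum to the simulated spectral
#' counts), a clinical CSV, a network TSV and a truth JSON. Files round-trip
#' through the readers in this package.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sites_global = file.path(dir, "Phospho (STY)Sites_global.txt"),
    sites_py = file.path(dir, "Phospho (STY)Sites_pY.txt"),
    peptides = file.path(dir, "modificationSpecificPeptides.txt"),
    evidence = file.path(dir, "evidence.txt"),
    clinical = file.path(dir, "clinical.csv"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.json"))

  write_sites_tsv(cohort$sites_global, paths["sites_global"])
  write_sites_tsv(cohort$sites_py, paths["sites_py"])

  ev <- cohort$evidence
  pep_tab <- data.frame(
    `Modified sequence` = ev$peptides$modified_sequence,
    Proteins = ev$peptides$proteins, check.names = FALSE,
    stringsAsFactors = FALSE)
  pint <- ev$intensity
  colnames(pint) <- paste("Intensity", colnames(pint))
  write.table(cbind(pep_tab, as.data.frame(pint, check.names = FALSE)),
              paths["peptides"], sep = "\t", quote = FALSE, row.names = FALSE)

  # evidence rows: split counts >= 2 into two rows to exercise aggregation
  idx <- which(ev$counts > 0, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ct <- ev$counts[i, j]
    parts <- if (ct >= 2) c(floor(ct / 2), ceiling(ct / 2)) else ct
    data.frame(
      `Modified sequence` = ev$peptides$modified_sequence[i],
      Proteins = ev$peptides$proteins[i],
      `Positions within proteins` = ev$peptides$positions[i],
      Experiment = colnames(ev$counts)[j],
      `MS/MS count` = parts,
      Intensity = ev$intensity[i, j] / length(parts),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  ev_tab <- do.call(rbind, rows)
  ev_tab <- ev_tab[order(ev_tab$`Modified sequence`, ev_tab$Experiment), ]
  write.table(ev_tab, paths["evidence"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  write.csv(cohort$clinical, paths["clinical"], row.names = FALSE,
            quote = FALSE)
  write_network_tsv(cohort$truth$network, paths["network"])

  tr <- cohort$truth
  jsonlite::write_json(list(
    subtype_labels = as.list(tr$subtype_labels),
    kinase_subtypes = as.list(tr$kinase_subtypes),
    prognostic_kinase = tr$prognostic_kinase,
    hyper_kinase = tr$hyper_kinase,
    py_samples = tr$py_samples,
    missingness = list(gamma0 = tr$config$missing_gamma0,
                       gamma1 = tr$config$missing_gamma1),
    hazard_beta = tr$config$hazard_beta,
    seed = tr$config$seed), paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_sites_tsv <- function(m, path) {
  int <- m$intensity
  int[is.na(int)] <- 0
  colnames(int) <- paste("Intensity", colnames(int))
  tab <- data.frame(
    Protein = m$annot$protein, `Gene names` = m$annot$gene,
    Position = m$annot$position, `Amino acid` = m$annot$residue,
    `Sequence window` = m$annot$window,
    `Localization prob` = m$annot$loc_prob,
    Multiplicity = m$annot$multiplicity,
    Reverse = ifelse(m$annot$reverse, "+", ""),
    `Potential contaminant` = ifelse(m$annot$contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cbind(tab, as.data.frame(int, check.names = FALSE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_network_tsv <- function(net, path) {
  sub <- data.frame(kinase = net$edges$kinase,
                    substrate = net$edges$substrate,
                    position = net$edges$position,
                    residue = net$edges$residue,
                    source = net$edges$source,
                    score = ifelse(is.na(net$edges$score), "",
                                   net$edges$score),
                    stringsAsFactors = FALSE)
  own <- data.frame(kinase = net$self_sites$kinase,
                    substrate = net$self_sites$protein,
                    position = net$self_sites$position,
                    residue = net$self_sites$residue,
                    source = ifelse(net$self_sites$activation_loop,
                                    "activation_loop", "self"),
                    score = "", stringsAsFactors = FALSE)
  write.table(rbind(sub, own), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
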