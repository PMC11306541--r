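#' Pipeline configuration
#'
#' Bundles every stage's settings with a single global seed. All analysis
#' thresholds are configuration, not hard-coded: class-I localization 0.75,
#' data presence 0.10, MAD top fraction 0.10, FDR 0.05, fold change 2,
#' signature size bounds 5-1000, top-20 kinase slice, and an optional
#' overall-survival cutoff override for the outcome-group split.
#'
#' @param sim a [sim_config()] describing the cohort (its seed is re-derived
#'   from the global seed).
#' @param out_dir output directory for fixture files and the report.
#' @param class1_threshold localization-probability cutoff.
#' @param dp_fraction data-presence fraction for feature filtering.
#' @param mad_top_fraction MAD top fraction feeding consensus clustering.
#' @param k_range,n_resamples,subsample_fraction consensus settings.
#' @param q_max,fc_min differential gates (BH FDR and ratio fold change).
#' @param sig_min_size,sig_max_size enrichment signature size bounds.
#' @param top_n_kinases ranked-profile slice size.
#' @param nwk_min_score predicted-edge score cutoff for INKA.
#' @param os_cutoff optional OS cutoff in months; when `NULL` the bimodal
#'   cutoff is estimated from the cohort (median OS if unimodal).
#' @param naive_only restrict outcome groups to treatment-naive patients.
#' @param seed global integer seed; fans out to per-stage seeds via a
#'   counter-based scheme so adding a stage never perturbs earlier stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("phoskin"),
                            class1_threshold = 0.75, dp_fraction = 0.10,
                            mad_top_fraction = 0.10, k_range = 2:6,
                            n_resamples = 250L, subsample_fraction = 0.8,
                            q_max = 0.05, fc_min = 2.0,
                            sig_min_size = 5L, sig_max_size = 1000L,
                            top_n_kinases = 20L, nwk_min_score = 2.0,
                            os_cutoff = NULL, naive_only = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$q_max <= 0 || cfg$q_max > 1) stop("q_max must lie in (0, 1]")
  if (cfg$fc_min < 1) stop("fc_min must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulate -> write fixture -> ingest -> preprocess -> subtype -> diff ->
#' enrich -> INKA -> survival, writing a machine-readable JSON report with
#' every seed and threshold needed for an exact rerun. Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return The report (a list), invisibly; also written to
#'   `file.path(cfg$out_dir, "report.json")`.
#' @export
run_all <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate and serialize the cohort -----------------------------------
  sim_cfg <- cfg$sim
  sim_cfg$seed <- stage_seed(cfg$seed, 1)
  cohort <- run_stage("simulate", simulate_cohort(sim_cfg))
  fix_dir <- file.path(cfg$out_dir, "fixture")
  paths <- run_stage("write_fixture", write_fixture(cohort, fix_dir))

  # -- ingest through the readers ------------------------------------------
  ing <- run_stage("ingest", {
    list(g = read_sites(paths["sites_global"], "global_pST"),
         y = read_sites(paths["sites_py"], "pY"),
         ev = spectral_counts_from_evidence(paths["evidence"]),
         net = read_network(paths["network"]),
         clinical = read_clinical(paths["clinical"]))
  })

  # -- preprocess -----------------------------------------------------------
  prep <- run_stage("preprocess", {
    g <- filter_class1(exclude_records(ing$g), cfg$class1_threshold)
    y <- filter_class1(exclude_records(ing$y), cfg$class1_threshold)
    g <- normalize_median_site(g)
    lysate <- colSums(ing$ev$counts)
    y <- normalize_total_count(y, lysate)
    g_dp <- filter_data_presence(g, cfg$dp_fraction)
    g_log <- log2_prepare(g_dp)
    g_sel <- select_most_variable_mad(g_log, cfg$mad_top_fraction)
    qc <- qc_correlations(g, ing$clinical)
    list(g = g, y = y, g_dp = g_dp, g_log = g_log, g_sel = g_sel, qc = qc)
  })

  # -- subtype --------------------------------------------------------------
  subty <- run_stage("subtype", consensus_cluster(
    prep$g_sel, k_range = cfg$k_range, n_resamples = cfg$n_resamples,
    subsample_fraction = cfg$subsample_fraction,
    seed = stage_seed(cfg$seed, 2)))
  labels <- subty$labels

  # -- differential statistics ---------------------------------------------
  diffs <- run_stage("diffstat", {
    res3 <- moderated_test(prep$g_log, labels)
    sig3 <- significant_features(res3, cfg$q_max, cfg$fc_min)
    cl <- ing$clinical
    tp53 <- setNames(ifelse(cl$tp53_status == 1, "mut", "wt"), cl$sample_id)
    res_tp53 <- moderated_test(prep$g_log, tp53)
    sig_tp53 <- significant_features(res_tp53, cfg$q_max, cfg$fc_min)
    g12d <- setNames(ifelse(cl$kras_allele == "G12D", "G12D", "other"),
                     cl$sample_id)
    res_g12d <- if (length(unique(g12d)) == 2L &&
                    min(table(g12d)) >= 2L)
      moderated_test(prep$g_log, g12d) else NULL
    list(res3 = res3, sig3 = sig3, res_tp53 = res_tp53,
         sig_tp53 = sig_tp53, res_g12d = res_g12d)
  })

  # -- enrichment (site signatures derived from the network) ---------------
  enr <- run_stage("enrich", {
    sigs <- network_site_signatures(ing$net, prep$g)
    es <- ptm_sea_score(prep$g, sigs, min_size = cfg$sig_min_size,
                        max_size = cfg$sig_max_size)
    list(es = es, cluster_means = average_by_cluster(es, labels))
  })

  # -- INKA -----------------------------------------------------------------
  inka <- run_stage("inka", {
    cg <- site_spectral_counts(ing$ev, prep$g)
    cy <- site_spectral_counts(ing$ev, prep$y)
    prof_g <- inka_sample_profiles(cg, ing$net, cfg$nwk_min_score, "pST")
    prof_y <- inka_sample_profiles(cy, ing$net, cfg$nwk_min_score, "pY")
    smat_g <- inka_score_matrix(prof_g)
    smat_y <- inka_score_matrix(prof_y)
    grp_g <- group_profile(cg, ing$net, labels, cfg$nwk_min_score, "pST")
    grp_y <- group_profile(cy, ing$net, labels[colnames(cy)],
                           cfg$nwk_min_score, "pY")
    two <- names(sort(table(labels), decreasing = TRUE))[1:2]
    cmp <- compare_profiles(
      smat_g[, names(labels)[labels %in% as.integer(two)], drop = FALSE],
      labels)
    list(smat_g = smat_g, smat_y = smat_y, grp_g = grp_g, grp_y = grp_y,
         top_g = lapply(grp_g, top_n, cfg$top_n_kinases),
         top_y = lapply(grp_y, top_n, cfg$top_n_kinases), cmp = cmp)
  })

  # -- survival -------------------------------------------------------------
  surv <- run_stage("survival", {
    cl <- ing$clinical
    assoc <- spearman_survival(inka$smat_g, cl, naive_only = FALSE)
    cutoff <- cfg$os_cutoff %||% bimodal_cutoff(cl$os_months)
    cutoff_src <- if (!is.null(cfg$os_cutoff)) "configured"
                  else if (is.na(cutoff)) "median (unimodal)" else "bimodal"
    if (is.na(cutoff)) cutoff <- median(cl$os_months)
    grp <- define_outcome_groups(cl, cutoff, cfg$naive_only)
    ext <- extreme_group_diff(prep$g_log, grp)
    km <- km_estimate(cl$os_months, cl$event_flag)
    two <- as.integer(names(sort(table(labels), decreasing = TRUE))[1:2])
    in2 <- cl$sample_id %in% names(labels)[labels %in% two]
    lr <- logrank_test(cl$os_months[in2], cl$event_flag[in2],
                       labels[cl$sample_id[in2]])
    list(assoc = assoc, cutoff = cutoff, cutoff_src = cutoff_src,
         groups = grp, extreme = ext, km = km, logrank = lr)
  })

  report <- list(
    parameters = list(
      seed = cfg$seed, class1_threshold = cfg$class1_threshold,
      dp_fraction = cfg$dp_fraction,
      mad_top_fraction = cfg$mad_top_fraction,
      n_resamples = cfg$n_resamples, q_max = cfg$q_max,
      fc_min = cfg$fc_min, nwk_min_score = cfg$nwk_min_score,
      top_n_kinases = cfg$top_n_kinases,
      sim_seed = sim_cfg$seed, n_samples = sim_cfg$n_samples),
    counts = list(
      sites_global_class1 = nrow(prep$g$intensity),
      sites_py_class1 = nrow(prep$y$intensity),
      sites_dp_filtered = nrow(prep$g_dp$intensity),
      sites_mad_selected = nrow(prep$g_sel$intensity)),
    qc = list(spearman_rho = prep$qc$spearman_rho,
              spearman_p = prep$qc$spearman_p),
    subtype = list(chosen_k = subty$chosen_k,
                   cdf_area = subty$cdf_area,
                   delta_area = subty$delta_area,
                   labels = as.list(labels)),
    diffstat = list(
      n_significant_3group = length(diffs$sig3),
      n_significant_tp53 = length(diffs$sig_tp53),
      d0 = attr(diffs$res3, "d0")),
    enrichment = list(cluster_means = as.data.frame(enr$cluster_means)),
    inka = list(
      top20_pst = lapply(inka$top_g, function(p)
        p[, c("kinase", "score", "rank", "dp_pct")]),
      top20_py = lapply(inka$top_y, function(p)
        p[, c("kinase", "score", "rank", "dp_pct")])),
    survival = list(
      cutoff_months = surv$cutoff, cutoff_source = surv$cutoff_src,
      n_short = length(surv$groups$short_ids),
      n_long = length(surv$groups$long_ids),
      n_extreme_significant = length(surv$extreme$significant),
      km_median = surv$km$median,
      logrank_p = surv$logrank$p,
      top_assoc = head(surv$assoc, 10)))

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(report = report, cohort = cohort, prep = prep,
                 subtype = subty, diff = diffs, enrich = enr, inka = inka,
                 survival = surv))
}

#' Site signatures derived from a kinase-substrate network
#'
#' One signature per kinase: the flanking windows of its substrate sites as
#' quantified in the site matrix. Used as bundled toy signatures for
#' site-level enrichment.
#'
#' @param net a `KinaseSubstrateNetwork`.
#' @param m a `SiteMatrix` providing the windows.
#' @return Named list of window vectors.
#' @export
network_site_signatures <- function(net, m) {
  keys <- site_key(m$annot)
  lookup <- setNames(m$annot$window, keys)
  edge_keys <- paste(net$edges$substrate, net$edges$position, sep = ":")
  sigs <- lapply(split(edge_keys, net$edges$kinase), function(kk) {
    w <- unname(lookup[intersect(unique(kk), keys)])
    unique(w[!is.na(w)])
  })
  sigs[vapply(sigs, length, 1L) > 0]
}
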