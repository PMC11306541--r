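test_that("simulated network has the forced edge and self-site counts", {
  ns <- simulate_network(2, 10, 3, predicted_fraction = 0.5, seed = 1)
  net <- ns$network
  expect_equal(nrow(net$edges), 6)
  expect_equal(sum(!net$self_sites$activation_loop), 2)
  expect_equal(sum(net$self_sites$activation_loop), 2)
  expect_equal(vapply(split(net$self_sites$activation_loop,
                            net$self_sites$kinase), sum, 1L),
               c(KIN01 = 1L, KIN02 = 1L))
  expect_true(all(is.finite(net$edges$score[net$edges$source == "predicted"])))

  all_cur <- simulate_network(3, 12, 4, predicted_fraction = 0, seed = 2)
  expect_true(all(all_cur$network$edges$source == "curated"))

  expect_error(simulate_network(2, 3, 5, seed = 1), "edges_per_kinase")
})

test_that("network simulation is deterministic under a fixed seed", {
  a <- simulate_network(4, 30, 5, 0.4, seed = 9)
  b <- simulate_network(4, 30, 5, 0.4, seed = 9)
  expect_identical(a, b)
  c <- simulate_network(4, 30, 5, 0.4, seed = 10)
  expect_false(identical(a$network$edges, c$network$edges))
})

test_that("cohort simulation is reproducible and respects the config", {
  cfg <- sim_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(ncol(a$sites_global$intensity), cfg$n_samples)
  expect_equal(ncol(a$sites_py$intensity),
               cfg$n_samples - round(cfg$py_channel_dropout * cfg$n_samples))
  expect_equal(sort(unique(a$truth$subtype_labels)), 1:3)
  expect_true(all(a$clinical$os_months > 0))
  expect_true(all(is.finite(a$truth$activities)))
  # roughly 90% of sites are class I by construction
  cls <- mean(a$sites_global$annot$loc_prob >= 0.75)
  expect_gt(cls, 0.8)
  expect_lt(cls, 0.97)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(mut_freq_kras = 1.2), "mut_freq_kras")
  expect_error(sim_config(n_subtypes = 1), "n_subtypes")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_kinases = 0), "n_kinases")
})

test_that("missingness is intensity-dependent (MNAR, low intensities drop)", {
  co <- simulate_cohort(sim_config(seed = 3))
  tr <- co$truth
  # mean true log2 intensity of observed entries exceeds that of missing ones
  expect_gt(mean(tr$log_intensity[tr$observed]),
            mean(tr$log_intensity[!tr$observed]))
  # and the gap closes when the slope is 0 (missing completely at random)
  co0 <- simulate_cohort(sim_config(missing_gamma1 = 0, missing_gamma0 = 1.5,
                                    seed = 3))
  gap0 <- mean(co0$truth$log_intensity[co0$truth$observed]) -
    mean(co0$truth$log_intensity[!co0$truth$observed])
  expect_lt(abs(gap0), 0.2)
})

test_that("planted subtype effect is detectable in kinase activities", {
  # two-sample t on a[k, s] between the kinase's subtype and the rest
  # rejects at alpha = 0.05 for activity_shift >= 2 in nearly all replicates
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(activity_shift = 2, seed = 1000 + r)
    co <- simulate_cohort(cfg)
    tr <- co$truth
    k <- "KIN05"
    in_sub <- tr$subtype_labels == tr$kinase_subtypes[k]
    p <- t.test(tr$activities[k, in_sub], tr$activities[k, !in_sub])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("mutation frequencies match the configured rates", {
  n_mut <- 0L
  for (r in 1:10) {
    co <- simulate_cohort(sim_config(seed = 50 + r))
    n_mut <- n_mut + sum(co$clinical$kras_status)
  }
  # 420 draws at 0.952: expect ~400, allow 4 binomial SDs (~17)
  expect_gt(n_mut, 400 - 18)
  expect_lt(n_mut, 420)
})

test_that("fixture files round-trip through the readers", {
  co <- simulate_cohort(sim_config(seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, dir)
  expect_true(all(file.exists(paths)))

  g <- read_sites(paths[["sites_global"]], "global_pST")
  expect_equal(dim(g$intensity), dim(co$sites_global$intensity))
  expect_equal(g$intensity, co$sites_global$intensity, tolerance = 1e-6)
  expect_equal(g$annot$loc_prob, co$sites_global$annot$loc_prob)
  expect_equal(rownames(g$intensity), rownames(co$sites_global$intensity))

  # truth JSON labels every sample
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_setequal(names(truth$subtype_labels),
                  colnames(co$sites_global$intensity))

  # evidence MS/MS counts re-aggregate to the simulated spectral counts
  ev <- spectral_counts_from_evidence(paths[["evidence"]])
  sim <- co$evidence$counts
  sim <- sim[rowSums(sim) > 0, , drop = FALSE]
  expect_setequal(rownames(ev$counts), rownames(sim))
  common <- intersect(colnames(ev$counts), colnames(sim))
  expect_equal(ev$counts[rownames(sim), common], sim[, common],
               ignore_attr = TRUE)
})

test_that("identical seed and config give identical fixture files", {
  co <- simulate_cohort(sim_config(seed = 33))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture(co, d1); p2 <- write_fixture(simulate_cohort(
    sim_config(seed = 33)), d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
})

test_that("null prognostic effect gives near-zero survival correlation", {
  rhos <- vapply(1:15, function(r) {
    co <- simulate_cohort(sim_config(hazard_beta = 0, seed = 400 + r))
    a <- co$truth$activities[co$truth$config$prognostic_kinase, ]
    cor(a, co$clinical$os_months, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})
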