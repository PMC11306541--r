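test_that("median-site normalization equalizes per-sample medians", {
  m <- toy_sites(n_samples = 3, n_sites = 5)
  # force per-sample medians 10, 20, 40 -> scale factors 2, 1, 0.5
  m$intensity <- matrix(rep(c(10, 20, 40), each = 5), 5, 3,
                        dimnames = dimnames(m$intensity))
  out <- normalize_median_site(m)
  expect_equal(unname(attr(out, "scale_factors")), c(2, 1, 0.5))
  meds <- apply(out$intensity, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(20, 3))

  # already-equal medians: identity
  m$intensity[] <- 20
  expect_equal(normalize_median_site(m)$intensity, m$intensity)

  # single sample: its own median is the target
  m1 <- toy_sites(n_samples = 4, n_sites = 5)
  m1$intensity <- m1$intensity[, 1, drop = FALSE]
  expect_equal(normalize_median_site(m1)$intensity, m1$intensity)

  # normalization never touches missing entries
  m2 <- toy_sites(n_samples = 3, n_sites = 6)
  m2$intensity[1, 2] <- NA
  expect_true(is.na(normalize_median_site(m2)$intensity[1, 2]))
  # all-missing sample errors by name
  m2$intensity[, 3] <- NA
  expect_error(normalize_median_site(m2), "S03")
})

test_that("per-sample observed medians agree after normalization", {
  co <- simulate_cohort(sim_config(seed = 5))
  out <- normalize_median_site(co$sites_global)
  meds <- apply(out$intensity, 2, median, na.rm = TRUE)
  expect_lt(diff(range(meds)) / meds[1], 1e-9)
})

test_that("total-count normalization scales by mean total over sample total", {
  m <- toy_sites(n_samples = 2, n_sites = 5, channel = "pY")
  m$intensity[] <- 100
  out <- normalize_total_count(m, c(S01 = 100, S02 = 200))
  expect_equal(unname(out$intensity[1, ]), c(150, 75))
  # equal totals: identity
  same <- normalize_total_count(m, c(S01 = 7, S02 = 7))
  expect_equal(same$intensity, m$intensity)
  expect_error(normalize_total_count(m, c(S01 = 100)), "S02")
  expect_error(normalize_median_site(m), "global_pST")
})

test_that("data-presence filter is inclusive and nested", {
  mat <- matrix(NA_real_, 3, 42,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:42)))
  mat[1, 1:4] <- 1    # 4/42 = 9.5% -> dropped at 10%
  mat[2, 1:5] <- 1    # 5/42 = 11.9% -> kept
  mat[3, ] <- 1       # complete
  out <- filter_data_presence(mat, 0.10)
  expect_equal(rownames(out), c("f2", "f3"))
  expect_equal(rownames(filter_data_presence(mat, 1.0)), "f3")

  # nesting: a stricter filter keeps a subset
  set.seed(1)
  big <- matrix(rnorm(200 * 20), 200, 20)
  big[sample(length(big), 2000)] <- NA
  rownames(big) <- paste0("f", 1:200)
  for (f1 in c(0.1, 0.3, 0.5)) {
    f2 <- f1 + 0.3
    expect_true(all(rownames(filter_data_presence(big, f2)) %in%
                      rownames(filter_data_presence(big, f1))))
  }
})

test_that("MAD selection ranks by median absolute deviation with ties stable", {
  mat <- rbind(a = c(1, 2, 3, 4, 100),   # MAD 1
               b = c(0, 0, 0, 0, 0),     # constant, MAD 0
               c = c(1, 5, 9, 13, 17))   # MAD 4
  colnames(mat) <- paste0("s", 1:5)
  top1 <- select_most_variable_mad(mat, 0.2)
  expect_equal(rownames(top1), "c")
  # ceiling count: 20 features at 0.1 -> 2 features
  m20 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(paste0("f", 1:20),
                                                      paste0("s", 1:6)))
  expect_equal(nrow(select_most_variable_mad(m20, 0.1)), 2)
  # MAD of {1,2,3,4,100} is 1 (median 3, abs devs {2,1,0,1,97})
  expect_equal(median(abs(mat["a", ] - median(mat["a", ]))), 1)
  # sample order invariance
  perm <- sample(ncol(m20))
  expect_equal(rownames(select_most_variable_mad(m20[, perm], 0.3)),
               rownames(select_most_variable_mad(m20, 0.3)))
  # shared multiplicative factor (shift after log2) leaves selection alone
  expect_equal(rownames(select_most_variable_mad(m20 + 5, 0.3)),
               rownames(select_most_variable_mad(m20, 0.3)))
})

test_that("log2 transform preserves missingness and order", {
  mat <- matrix(c(8, NA, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                      c("x", "y")))
  out <- log2_prepare(mat)
  expect_equal(out["a", "x"], 3)
  expect_true(is.na(out["b", "x"]))
  expect_true(is.na(out["b", "y"]))  # zero treated as unobserved
  set.seed(2)
  v <- matrix(sort(2^runif(10, 1, 5)), 1)
  colnames(v) <- paste0("s", 1:10)
  expect_equal(order(log2_prepare(v)), order(v))
})

test_that("qc correlations recover monotone cellularity relationships", {
  m <- toy_sites(n_samples = 3, n_sites = 10)
  m$intensity[4:10, 1] <- NA  # 3 sites observed
  m$intensity[7:10, 2] <- NA  # 6 sites
  clin <- data.frame(sample_id = c("S01", "S02", "S03"),
                     cellularity_pct = c(10, 40, 70))
  qc <- qc_correlations(m, clin)
  expect_equal(unname(qc$id_counts), c(3, 6, 10))
  expect_equal(qc$spearman_rho, 1)
  clin$cellularity_pct <- c(70, 40, 10)
  expect_equal(qc_correlations(m, clin)$spearman_rho, -1)
  # constant counts: not assessable
  m$intensity[] <- 5
  expect_true(is.na(qc_correlations(m, clin)$spearman_rho))
})

test_that("cellularity-scaled cohorts give positive qc correlation", {
  hits <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(sim_config(seed = 700 + r))
    m <- co$sites_global
    # emulate cellularity-driven identification depth: drop sites in
    # low-cellularity samples
    cell <- co$clinical$cellularity_pct
    set.seed(r)
    for (j in seq_along(cell)) {
      p_drop <- 0.4 * (1 - cell[j] / 70)
      drop <- runif(nrow(m$intensity)) < p_drop
      m$intensity[drop, j] <- NA
    }
    qc <- qc_correlations(m, co$clinical)
    hits <- hits + (qc$spearman_rho > 0 && qc$spearman_p < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})
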