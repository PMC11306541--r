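toy_counts <- function() {
  keys <- c("KAP:100", "KAP:200", "KBP:100", "KBP:200",
            "P1:10", "P1:20", "P2:5", "P3:7")
  m <- matrix(0L, length(keys), 2, dimnames = list(keys, c("u1", "u2")))
  m[, "u1"] <- c(3L, 2L, 0L, 0L, 1L, 1L, 4L, 6L)
  m[, "u2"] <- c(5L, 0L, 2L, 1L, 0L, 2L, 0L, 3L)
  m
}

test_that("evidence arms sum the right sites into the right arms", {
  net <- toy_network()
  arms <- build_evidence_arms(toy_counts(), net, "u1")
  ka <- arms[arms$kinase == "KA", ]
  # self 3 (act loop 2 separate), curated P1:10 + P1:20 = 2,
  # predicted P2:5 score 3 >= 2 -> 4
  expect_equal(ka$c_kin, 3)
  expect_equal(ka$c_act, 2)
  expect_equal(ka$c_psp, 2)
  expect_equal(ka$c_nwk, 4)
  kb <- arms[arms$kinase == "KB", ]
  # curated P2:5 = 4; predicted P3:7 score 1.9 < 2 -> excluded
  expect_equal(kb$c_psp, 4)
  expect_equal(kb$c_nwk, 0)
})

test_that("predicted edges at or above the cutoff count, below do not", {
  net <- toy_network()
  arms2 <- build_evidence_arms(toy_counts(), net, "u1", nwk_min_score = 3.0)
  expect_equal(arms2$c_nwk[arms2$kinase == "KA"], 4)  # score 3.0 inclusive
  arms3 <- build_evidence_arms(toy_counts(), net, "u1", nwk_min_score = 3.1)
  expect_equal(arms3$c_nwk[arms3$kinase == "KA"], 0)
})

test_that("a site with both curated and predicted edges counts once (curated)", {
  net <- toy_network()
  # give KA a predicted edge onto its own curated substrate P1:10
  net$edges <- rbind(net$edges,
                     data.frame(kinase = "KA", substrate = "P1",
                                position = 10L, residue = "S",
                                source = "predicted", score = 5,
                                stringsAsFactors = FALSE))
  arms <- build_evidence_arms(toy_counts(), net, "u1")
  ka <- arms[arms$kinase == "KA", ]
  expect_equal(ka$c_psp, 2)  # unchanged
  expect_equal(ka$c_nwk, 4)  # P1:10 not double counted
})

test_that("INKA scores integrate arms geometrically with stated exclusions", {
  arms <- data.frame(kinase = c("K1", "K2", "K3"),
                     c_kin = c(10, 4, 0), c_act = c(6, 0, 0),
                     c_psp = c(2, 0, 5), c_nwk = c(2, 0, 0))
  prof <- inka_score(arms)
  # K = 16, S = 4 -> score 8
  expect_equal(prof$score[prof$kinase == "K1"], 8)
  # K > 0, S = 0: excluded from ranking, listed kinase-centric-only
  expect_false("K2" %in% prof$kinase)
  expect_equal(attr(prof, "kinase_centric_only"), "K2")
  # K = 0: scores 0, stays ranked at the bottom
  expect_equal(prof$score[prof$kinase == "K3"], 0)
  expect_equal(prof$rank, seq_len(nrow(prof)))
})

test_that("score ties are broken alphabetically in ranks and top_n", {
  arms <- data.frame(kinase = c("B", "A", "C"),
                     c_kin = c(16, 16, 1), c_act = 0,
                     c_psp = c(4, 4, 4), c_nwk = 0)
  prof <- inka_score(arms)
  expect_equal(prof$kinase, c("A", "B", "C"))
  t5 <- top_n(prof, 20)
  expect_equal(nrow(t5), 3)
  expect_match(attr(t5, "note"), "3 kinases")
  expect_equal(top_n(prof, 2)$kinase, c("A", "B"))
})

test_that("arms and scores match the brute-force oracle on small networks", {
  set.seed(17)
  for (r in 1:12) {
    n_kin <- sample(2:5, 1)
    n_sites <- sample(8:20, 1)
    ns <- simulate_network(n_kin, n_sites, sample(2:5, 1),
                           predicted_fraction = runif(1), seed = 300 + r)
    net <- ns$network
    keys <- unique(c(paste(ns$sites$protein, ns$sites$position, sep = ":"),
                     paste(net$self_sites$protein, net$self_sites$position,
                           sep = ":")))
    counts <- matrix(rpois(length(keys), 4), length(keys), 1,
                     dimnames = list(keys, "u"))
    arms <- build_evidence_arms(counts, net, "u")
    oracle <- oracle_inka_arms(setNames(counts[, 1], keys), net)
    expect_equal(arms, oracle)
    prof <- inka_score(arms)
    K <- oracle$c_kin + oracle$c_act
    S <- oracle$c_psp + oracle$c_nwk
    exp_score <- sqrt(K * S)
    keep <- !(K > 0 & S == 0)
    expect_equal(sort(prof$score), sort(exp_score[keep]))
  }
})

test_that("scores are scale-equivariant and monotone in evidence", {
  net <- toy_network()
  counts <- toy_counts()
  p1 <- inka_score(build_evidence_arms(counts, net, "u1"))
  p3 <- inka_score(build_evidence_arms(counts * 3L, net, "u1"))
  expect_equal(p3$score, 3 * p1$score)
  expect_equal(p3$kinase, p1$kinase)
  # adding evidence to any arm never decreases the score
  arms <- build_evidence_arms(counts, net, "u1")
  score_of <- function(a, k) {
    p <- inka_score(a)
    p$score[p$kinase == k]
  }
  base <- score_of(arms, "KA")
  for (col in c("c_kin", "c_act", "c_psp", "c_nwk")) {
    bumped <- arms
    bumped[[col]][bumped$kinase == "KA"] <-
      bumped[[col]][bumped$kinase == "KA"] + 5
    expect_gte(score_of(bumped, "KA"), base)
  }
})

test_that("group profiles pool evidence and annotate data presence", {
  net <- toy_network()
  counts <- toy_counts()
  # single-sample group equals the sample profile
  gp <- group_profile(counts, net, c(u1 = "g1", u2 = "g2"))
  sp <- inka_score(build_evidence_arms(counts, net, "u1"), unit = "g1")
  expect_equal(gp$g1$score, sp$score)
  expect_equal(gp$g1$kinase, sp$kinase)
  # two identical samples double every score, ranks unchanged
  cc <- cbind(counts[, "u1", drop = FALSE],
              u1b = counts[, "u1"])
  gp2 <- group_profile(cc, net, c(u1 = "g", u1b = "g"))
  expect_equal(gp2$g$score, 2 * sp$score)
  expect_equal(gp2$g$kinase, sp$kinase)
  expect_true(all(gp2$g$dp_pct %in% c(0, 100)))
  # DP arithmetic: 14 of 42 samples -> 33%
  expect_equal(round(100 * 14 / 42), 33)
})

test_that("profile comparison flags planted differential kinases", {
  set.seed(23)
  reps <- 20L
  hits <- 0L
  for (r in seq_len(reps)) {
    smat <- matrix(rexp(2 * 24, rate = 0.1), 2, 24,
                   dimnames = list(c("KUP", "KNULL"), paste0("s", 1:24)))
    labs <- setNames(rep(c("A", "B"), each = 12), colnames(smat))
    smat["KUP", labs == "A"] <- smat["KUP", labs == "A"] * 8
    cmp <- compare_profiles(smat, labs)
    row <- cmp[cmp$kinase == "KUP", ]
    hits <- hits + (row$q < 0.05 && row$higher_in == "A")
  }
  expect_gte(hits / reps, 0.9)
  # identical groups: no significance
  smat <- matrix(rep(1:12, 2), 2, 12, byrow = TRUE,
                 dimnames = list(c("K1", "K2"), paste0("s", 1:12)))
  labs <- setNames(rep(c("A", "B"), 6), colnames(smat))
  cmp0 <- compare_profiles(smat, labs)
  expect_true(all(cmp0$p > 0.5))
  # all-zero kinases are skipped
  smat["K2", ] <- 0
  expect_false("K2" %in% compare_profiles(smat, labs)$kinase)
})

test_that("site-level spectral counts aggregate peptides onto sites", {
  m <- toy_sites(n_samples = 2, n_sites = 3)
  peptides <- data.frame(
    modified_sequence = c("_A_", "_B_"),
    proteins = c("P1", "P1;P2"),
    positions = c("10", "10;20"),
    stringsAsFactors = FALSE)
  counts <- matrix(c(2L, 1L, 3L, 4L), 2, 2,
                   dimnames = list(c("_A_", "_B_"), c("S01", "S02")))
  ev <- peptide_evidence(peptides, counts)
  sc <- site_spectral_counts(ev, m)
  expect_equal(sc["P1:10", "S01"], 2L + 1L)
  expect_equal(sc["P2:20", "S02"], 4L)
  expect_equal(sc["P3:30", "S01"], 0L)
})
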