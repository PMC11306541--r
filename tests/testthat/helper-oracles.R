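# Independent oracles, deliberately naive: loop-based recomputations used to
# check the vectorized implementations.

# Brute-force ssGSEA running sum: walk the ranked list position by position.
oracle_ssgsea <- function(values, members, alpha) {
  ord <- order(-values)
  v <- values[ord]
  keys <- names(values)[ord]
  N <- length(v)
  inset <- keys %in% members
  m <- sum(inset)
  if (m == 0 || m == N) return(if (m == N) 0 else NA_real_)
  denom_in <- sum(abs(v[inset])^alpha)
  es <- 0
  run_in <- 0
  run_out <- 0
  for (i in seq_len(N)) {
    if (inset[i]) run_in <- run_in + abs(v[i])^alpha / denom_in
    else run_out <- run_out + 1 / (N - m)
    es <- es + (run_in - run_out)
  }
  unname(es)
}

# Step-up BH, written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force INKA arms: iterate every (kinase, site) relation explicitly.
oracle_inka_arms <- function(counts_vec, net, nwk_min_score = 2.0) {
  kin <- sort(unique(net$self_sites$kinase))
  out <- data.frame(kinase = kin, c_kin = 0, c_act = 0, c_psp = 0,
                    c_nwk = 0, stringsAsFactors = FALSE)
  val <- function(prot, pos) {
    key <- paste(prot, pos, sep = ":")
    if (key %in% names(counts_vec)) counts_vec[[key]] else 0
  }
  for (i in seq_len(nrow(out))) {
    k <- out$kinase[i]
    for (j in which(net$self_sites$kinase == k)) {
      v <- val(net$self_sites$protein[j], net$self_sites$position[j])
      if (net$self_sites$activation_loop[j]) out$c_act[i] <- out$c_act[i] + v
      else out$c_kin[i] <- out$c_kin[i] + v
    }
    cur_keys <- character(0)
    for (j in which(net$edges$kinase == k & net$edges$source == "curated")) {
      key <- paste(net$edges$substrate[j], net$edges$position[j], sep = ":")
      if (!key %in% cur_keys) {
        out$c_psp[i] <- out$c_psp[i] + val(net$edges$substrate[j],
                                           net$edges$position[j])
        cur_keys <- c(cur_keys, key)
      }
    }
    seen <- character(0)
    for (j in which(net$edges$kinase == k & net$edges$source == "predicted")) {
      if (is.na(net$edges$score[j]) || net$edges$score[j] < nwk_min_score)
        next
      key <- paste(net$edges$substrate[j], net$edges$position[j], sep = ":")
      if (key %in% cur_keys || key %in% seen) next
      out$c_nwk[i] <- out$c_nwk[i] + val(net$edges$substrate[j],
                                         net$edges$position[j])
      seen <- c(seen, key)
    }
  }
  out
}

# Small hand-built network used across tests: 2 kinases, explicit edges.
toy_network <- function() {
  edges <- data.frame(
    kinase = c("KA", "KA", "KA", "KB", "KB"),
    substrate = c("P1", "P1", "P2", "P2", "P3"),
    position = c(10L, 20L, 5L, 5L, 7L),
    residue = c("S", "S", "T", "T", "Y"),
    source = c("curated", "curated", "predicted", "curated", "predicted"),
    score = c(NA, NA, 3.0, NA, 1.9),
    stringsAsFactors = FALSE)
  self_sites <- data.frame(
    kinase = c("KA", "KA", "KB", "KB"),
    protein = c("KAP", "KAP", "KBP", "KBP"),
    position = c(100L, 200L, 100L, 200L),
    residue = c("S", "T", "Y", "Y"),
    activation_loop = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  kinase_network(edges, self_sites)
}

# Small in-memory SiteMatrix for IO/preprocess tests.
toy_sites <- function(n_samples = 4, n_sites = 6, seed = 42,
                      channel = "global_pST") {
  set.seed(seed)
  annot <- data.frame(
    protein = paste0("P", seq_len(n_sites)),
    gene = paste0("g", seq_len(n_sites)),
    position = 10L * seq_len(n_sites),
    residue = rep(c("S", "T", "Y"), length.out = n_sites),
    window = vapply(seq_len(n_sites), function(i) {
      r <- rep(c("S", "T", "Y"), length.out = n_sites)[i]
      fl <- paste(sample(strsplit("ACDEFGHIKLMNPQ", "")[[1]], 7,
                         replace = TRUE), collapse = "")
      paste0(fl, r, substr(paste0(fl, "AAAAAAA"), 1, 7))
    }, ""),
    loc_prob = seq(0.2, 1, length.out = n_sites),
    multiplicity = 1L, reverse = FALSE, contaminant = FALSE,
    stringsAsFactors = FALSE)
  int <- matrix(2^rnorm(n_sites * n_samples, 20, 1), n_sites, n_samples,
                dimnames = list(NULL, sprintf("S%02d", seq_len(n_samples))))
  site_matrix(annot, int, channel)
}

expect_ari_at_least <- function(labels, truth, min_ari) {
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(labels, truth)
  expect_gte(ari, min_ari)
}
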