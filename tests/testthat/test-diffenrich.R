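toy_cm <- function(t1) {
  filler <- matrix(100L, 30, 2)            # unchanged background peaks
  balance <- c(0L, sum(t1[1]) - sum(t1[2]))  # equalize library sizes
  m <- rbind(t1, filler, balance)
  rownames(m) <- paste0("pk", seq_len(nrow(m)))
  colnames(m) <- c("s_t", "s_r")
  count_matrix(m, c(s_t = "target", s_r = "reference"))
}

test_that("log2 fold change uses the +0.5 stabilizer on normalized means", {
  cm <- toy_cm(c(40L, 10L))
  dp <- select_differential_peaks(cm)
  # equal library sizes: normalized counts equal raw counts
  expect_equal(dp$log2_fc[1], log2(40.5 / 10.5))
})

test_that("identical conditions yield only unchanged calls", {
  m <- matrix(rep(c(5L, 50L, 500L), 2), 3, 2,
              dimnames = list(paste0("pk", 1:3), c("a", "b")))
  cm <- count_matrix(m, c(a = "target", b = "reference"))
  dp <- select_differential_peaks(cm)
  expect_true(all(dp$call == "unchanged"))
  expect_true(all(dp$log2_fc == 0))
})

test_that("swapping condition labels negates fold changes and mirrors calls", {
  m <- matrix(c(200L, 10L, 100L, 10L, 200L, 100L), 3, 2,
              dimnames = list(paste0("pk", 1:3), c("a", "b")))
  dp1 <- select_differential_peaks(count_matrix(m, c(a = "target", b = "reference")))
  dp2 <- select_differential_peaks(count_matrix(m, c(a = "reference", b = "target")))
  expect_equal(dp1$log2_fc, -dp2$log2_fc)
  expect_equal(dp1$p_value, dp2$p_value)
  swap <- c(target_specific = "reference_specific", unchanged = "unchanged",
            reference_specific = "target_specific")
  expect_equal(unname(swap[dp1$call]), dp2$call)
})

test_that("the pooled two-proportion p matches prop.test with continuity correction", {
  cases <- list(c(40, 1000, 10, 1000), c(3, 50, 9, 60), c(0, 80, 5, 90),
                c(120, 5000, 80, 4000))
  for (cs in cases) {
    got <- promforge:::two_prop_pvalue(cs[1], cs[2], cs[3], cs[4])
    want <- suppressWarnings(
      stats::prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]))$p.value)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("degenerate count matrices are rejected", {
  m0 <- matrix(0L, 2, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_error(select_differential_peaks(
    count_matrix(m0, c(a = "target", b = "reference"))), "all-zero")
  m1 <- matrix(c(1L, 2L, 0L, 0L), 2, 2,
               dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_error(select_differential_peaks(
    count_matrix(m1, c(a = "target", b = "reference"))), "zero total")
})

test_that("one-sided Fisher p equals the hypergeometric tail on all small tables", {
  for (N_t in 1:12) for (N_b in 1:12)
    for (n_t in 0:N_t) for (n_b in 0:N_b)
      expect_equal(fisher_enrichment_p(n_t, N_t, n_b, N_b),
                   hyper_tail_oracle(n_t, N_t, n_b, N_b), tolerance = 1e-12)
})

test_that("enrichment p agrees with fisher.test on spot checks", {
  for (cs in list(c(5, 10, 1, 10), c(8, 20, 3, 25), c(0, 10, 0, 10))) {
    tab <- matrix(c(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3]), 2, byrow = TRUE)
    expect_equal(fisher_enrichment_p(cs[1], cs[2], cs[3], cs[4]),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  for (seed in 1:5) {
    p <- with_fixed_seed(seed, runif(50)^2)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("motif_enrichment builds the ZOOPS table and sorts by significance", {
  lib <- toy_library()
  site <- consensus_site(lib$TFA)
  flank <- function(s) paste0(strrep("G", 10), s, strrep("G", 10))
  tseqs <- c(replicate(6, flank(site)), replicate(4, flank(strrep("C", 8))))
  bseqs <- replicate(10, flank(strrep("C", 8)))
  mk <- function(seqs, label) {
    ends <- cumsum(nchar(seqs))
    peak_set(data.frame(chrom = label, start = ends - nchar(seqs), end = ends,
                        name = sprintf("%s_%d", label, seq_along(seqs))),
             label = label, sequences = seqs)
  }
  res <- motif_enrichment(lib, mk(tseqs, "t"), mk(bseqs, "b"))
  row <- res[res$motif_id == "TFA", ]
  expect_equal(row$n_target, 6)
  expect_equal(row$N_target, 10)
  expect_equal(row$n_bg, 0)
  # Haldane-corrected fold when no background peak carries a hit
  expect_equal(row$fold_enrichment, (6.5 / 10) / (0.5 / 10))
  expect_equal(row$p_value, hyper_tail_oracle(6, 10, 0, 10), tolerance = 1e-12)
  expect_equal(res$motif_id[1], "TFA")   # sorted by p ascending
  expect_true(all(diff(res$p_value) >= 0))
  # motifs absent from both sets give p = 1
  expect_true(all(res$p_value[res$motif_id != "TFA"] == 1))
})

test_that("identical target and background give fold 1 and non-significant p", {
  lib <- toy_library()[1:2]
  ps <- simulate_background(30, 60, seed = 11)
  res <- motif_enrichment(lib, ps, ps)
  hit <- res$n_target > 0
  expect_equal(res$fold_enrichment[hit], rep(1, sum(hit)))
  expect_true(all(res$p_value >= 0.5))
})

test_that("a strongly planted motif is recovered with q < 0.05 in every replicate", {
  lib <- lapply(1:5, function(i) random_pwm(sprintf("P%d", i), width = 8,
                                            seed = 300 + i))
  lib <- unique_motif_ids(lib)
  hits <- vapply(1:20, function(rep) {
    tgt <- simulate_background(200, 200, seed = 40000 + rep)
    bg <- simulate_background(200, 200, seed = 41000 + rep)
    tgt <- plant_motifs(tgt, lib$P1, 0.6, seed = 42000 + rep)$peaks
    bg <- plant_motifs(bg, lib$P1, 0.05, seed = 43000 + rep)$peaks
    res <- motif_enrichment(lib, tgt, bg)
    res$q_value[res$motif_id == "P1"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
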