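# brute-force similarity sweep used as the oracle
sweep_similarity <- function(a, b) {
  colcor <- function(x, y) {
    if (sd(x) < 1e-12 || sd(y) < 1e-12) return(0)
    cor(x, y)
  }
  best <- -Inf
  for (orient in 1:2) {
    bm <- if (orient == 1) b$prob else {
      m <- b$prob[4:1, rev(seq_len(b$width)), drop = FALSE]
      rownames(m) <- c("A", "C", "G", "T"); m
    }
    for (d in -(b$width):(a$width)) {
      js <- max(1, 1 - d):min(b$width, a$width - d)
      if (length(js) < 4 || js[1] > js[length(js)]) next
      sim <- mean(vapply(js, function(j) colcor(a$prob[, j + d], bm[, j]), 0))
      best <- max(best, sim)
    }
  }
  best
}

test_that("identical motifs align perfectly at offset zero", {
  p <- random_pwm("ida", width = 8, seed = 7, dominance = 0.8)
  m <- motif_similarity(p, p)
  expect_equal(m$similarity, 1.0, tolerance = 1e-12)
  expect_equal(m$offset, 0L)
  expect_equal(m$orientation, "same")
})

test_that("a motif matches its reverse complement in the opposite orientation", {
  p <- sharp_pwm("rcm", "ACCGTTAT", p = 0.9)   # non-palindromic
  m <- motif_similarity(p, reverse_complement(p))
  expect_equal(m$similarity, 1.0, tolerance = 1e-12)
  expect_equal(m$orientation, "reverse_complement")
})

test_that("similarity equals the exhaustive offset/orientation sweep", {
  for (seed in 1:10) {
    a <- with_fixed_seed(seed, {
      m <- matrix(stats::rgamma(32, 0.8) + 0.01, 4, 8)
      pwm("a", sweep(m, 2, colSums(m), "/"))
    })
    b <- with_fixed_seed(100 + seed, {
      m <- matrix(stats::rgamma(32, 0.8) + 0.01, 4, 8)
      pwm("b", sweep(m, 2, colSums(m), "/"))
    })
    expect_equal(motif_similarity(a, b)$similarity, sweep_similarity(a, b),
                 tolerance = 1e-12)
  }
})

test_that("narrow motifs are rejected for similarity", {
  a <- random_pwm("w4", width = 4, seed = 1)
  b <- structure(list(id = "w3", width = 3, prob = matrix(1 / 4, 4, 3)),
                 class = "Pwm")
  expect_error(motif_similarity(a, b), "width >= 4")
})

fake_result <- function(ids, ps) {
  data.frame(motif_id = ids, tf_name = ids, n_target = 1, N_target = 10,
             n_bg = 0, N_bg = 10, fold_enrichment = 2,
             p_value = ps, q_value = ps)
}

test_that("by_id intersection keeps exactly the motifs significant everywhere", {
  r1 <- fake_result(c("BATF", "IRF4", "MYB"), c(0.01, 0.2, 0.001))
  r2 <- fake_result(c("batf", "IRF4", "MYB"), c(0.03, 0.01, 0.002))
  r3 <- fake_result(c("BATF", "ETS1", "MYB"), c(0.04, 0.01, 0.2))
  cs <- intersect_enriched(list(r1, r2, r3))
  # BATF: significant in all three (case-insensitive); IRF4 fails set 1,
  # MYB fails set 3, ETS1 absent from sets 1-2
  expect_equal(cs$canonical_id, "BATF")
  expect_equal(cs$id_2, "batf")
  expect_equal(attr(cs, "k"), 3)
  expect_error(intersect_enriched(list(r1)), ">= 2")
})

test_that("raising p_max only grows the conserved set", {
  r1 <- fake_result(c("A1", "B2", "C3"), c(0.01, 0.04, 0.3))
  r2 <- fake_result(c("A1", "B2", "C3"), c(0.02, 0.06, 0.2))
  sizes <- vapply(c(0.01, 0.03, 0.05, 0.1, 0.5), function(pm)
    nrow(intersect_enriched(list(r1, r2), p_max = pm)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("conserved sets are ordered by worst per-dataset p", {
  r1 <- fake_result(c("A1", "B2"), c(0.001, 0.002))
  r2 <- fake_result(c("A1", "B2"), c(0.04, 0.003))
  cs <- intersect_enriched(list(r1, r2))
  expect_equal(cs$canonical_id, c("B2", "A1"))   # max p: 0.003 < 0.04
})

test_that("by_similarity with identical libraries and sim_min 1 reduces to by_id", {
  lib <- unique_motif_ids(lapply(1:6, function(i)
    random_pwm(sprintf("S%d", i), width = 8, seed = 200 + i, dominance = 0.8)))
  ids <- names(lib)
  r1 <- fake_result(ids, c(0.01, 0.02, 0.3, 0.01, 0.04, 0.6))
  r2 <- fake_result(ids, c(0.02, 0.4, 0.01, 0.03, 0.01, 0.01))
  by_id <- intersect_enriched(list(r1, r2), match_mode = "by_id")
  by_sim <- intersect_enriched(list(r1, r2), libraries = list(lib, lib),
                               match_mode = "by_similarity", sim_min = 1.0)
  expect_setequal(by_id$canonical_id, by_sim$canonical_id)
  expect_equal(by_sim$id_1, by_sim$id_2)   # each motif matched to itself
})

test_that("by_similarity matches renamed cross-library motifs", {
  lib1 <- unique_motif_ids(lapply(1:4, function(i)
    random_pwm(sprintf("mouse_%d", i), width = 8, seed = 500 + i)))
  lib2 <- unique_motif_ids(lapply(1:4, function(i)
    random_pwm(sprintf("human_%d", i), width = 8, seed = 500 + i)))
  r1 <- fake_result(names(lib1), rep(0.01, 4))
  r2 <- fake_result(names(lib2), rep(0.01, 4))
  cs <- intersect_enriched(list(r1, r2), libraries = list(lib1, lib2),
                           match_mode = "by_similarity", sim_min = 0.8)
  expect_equal(nrow(cs), 4)
  expect_equal(sub("mouse", "human", cs$id_1), cs$id_2)
  expect_error(intersect_enriched(list(r1, r2), libraries = list(lib1, lib2),
                                  match_mode = "by_similarity", sim_min = 1.5),
               "sim_min")
})

test_that("output size never exceeds the smallest per-dataset enriched count", {
  for (seed in 1:5) {
    ids <- sprintf("T%d", 1:8)
    rs <- lapply(1:3, function(k)
      fake_result(ids, with_fixed_seed(seed * 10 + k, runif(8, 0, 0.2))))
    cs <- intersect_enriched(rs)
    min_enriched <- min(vapply(rs, function(r) sum(r$p_value < 0.05), 0))
    expect_lte(nrow(cs), min_enriched)
  }
})
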