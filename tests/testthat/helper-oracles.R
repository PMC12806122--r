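# Shared fixtures and independent oracles used across test files.

with_fixed_seed <- function(seed, expr) withr::with_seed(seed, expr)

revcomp_str <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# PWM with one near-certain base per column (explicit, no RNG)
sharp_pwm <- function(id, bases, p = 0.97) {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  prob <- matrix((1 - p) / 3, 4, length(idx))
  prob[cbind(idx, seq_along(idx))] <- p
  pwm(id, prob, tf_name = id)
}

# brute-force score distribution: enumerate all 4^W words
enum_distribution <- function(sm) {
  sc <- 0
  pr <- 1
  for (j in seq_len(sm$width)) {
    sc <- outer(as.vector(sc), sm$int_scores[, j], "+")
    pr <- outer(as.vector(pr), sm$background, "*")
  }
  agg <- tapply(as.vector(pr), as.vector(sc), sum)
  list(score = as.numeric(names(agg)), prob = unname(as.vector(agg)))
}

# naive per-window scanner: independent loop over windows and strands,
# discretizing each window score the same way the scoring matrix does
naive_scan_offsets <- function(pwm_obj, seq, t_int, background = rep(0.25, 4),
                               scale = 1000L) {
  score_one <- function(p, chars) {
    if (any(!chars %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_along(chars), function(j)
      round(log2(p$prob[chars[j], j] / background[match(chars[j], c("A","C","G","T"))]) * scale),
      0))
  }
  chars <- strsplit(seq, "")[[1]]
  W <- pwm_obj$width
  rc <- reverse_complement(pwm_obj)
  hits <- list()
  if (length(chars) >= W) {
    for (off in 0:(length(chars) - W)) {
      win <- chars[(off + 1):(off + W)]
      if (score_one(pwm_obj, win) >= t_int)
        hits[[length(hits) + 1]] <- c(off, 1L)
      if (score_one(rc, win) >= t_int)
        hits[[length(hits) + 1]] <- c(off, 2L)
    }
  }
  if (length(hits) == 0) return(data.frame(offset = integer(), strand = integer()))
  m <- do.call(rbind, hits)
  data.frame(offset = m[, 1], strand = m[, 2])
}

# hypergeometric enrichment tail by explicit choose() sums
hyper_tail_oracle <- function(n_t, N_t, n_b, N_b) {
  K <- n_t + n_b
  N <- N_t + N_b
  ks <- max(n_t, K - N_b):min(K, N_t)
  sum(choose(K, ks) * choose(N - K, N_t - ks)) / choose(N, N_t)
}

# Benjamini-Hochberg by the direct step-up formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# small shared motif library for design/pipeline tests
toy_library <- function() {
  # consensus strings chosen non-palindromic so a clean design has exactly
  # one own-motif hit per site (a reverse-palindrome would hit both strands)
  unique_motif_ids(list(
    sharp_pwm("TFA", "ACCGTAAT"),
    sharp_pwm("TFB", "GGATGGAT"),
    sharp_pwm("TFC", "TTACGCAA"),
    sharp_pwm("TFD", "CACGTG")))
}
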