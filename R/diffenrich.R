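#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a family of p-values, with
#' domain validation; values return in their original order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values (BH-adjusted p-values) in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select state-specific peaks from a two-condition count matrix
#'
#' Per-sample counts are scaled to a common effective library size (the mean
#' library size), condition means are computed with a +0.5 stabilizer, and
#' each peak is tested with a pooled two-proportion chi-square test with
#' continuity correction (peak count vs library remainder, target pool vs
#' reference pool). Peaks are called `target_specific` when
#' `log2_fc > log2(fc_min)` and BH q < `fdr_max`, mirrored for
#' `reference_specific`, else `unchanged`.
#'
#' @param cm A [count_matrix()].
#' @param fc_min Fold-change threshold (default 2, i.e. |log2 FC| > 1).
#' @param fdr_max BH FDR threshold (default 0.05).
#' @return data.frame with `peak_id`, `mean_target`, `mean_reference`
#'   (normalized), `log2_fc`, `p_value`, `q_value`, `call`.
#' @export
select_differential_peaks <- function(cm, fc_min = 2, fdr_max = 0.05) {
  stopifnot(inherits(cm, "CountMatrix"))
  counts <- cm$counts
  if (all(counts == 0)) stopf("select_differential_peaks: all-zero count matrix")
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("select_differential_peaks: sample(s) %s have zero total counts",
                           paste(colnames(counts)[lib == 0], collapse = ","))
  norm <- sweep(counts, 2, mean(lib) / lib, "*")
  tgt <- cm$condition == "target"
  mean_t <- rowMeans(norm[, tgt, drop = FALSE])
  mean_r <- rowMeans(norm[, !tgt, drop = FALSE])
  log2_fc <- log2((mean_t + 0.5) / (mean_r + 0.5))

  # pooled raw counts per condition for the two-proportion test
  x_t <- rowSums(counts[, tgt, drop = FALSE])
  x_r <- rowSums(counts[, !tgt, drop = FALSE])
  n_t <- sum(lib[tgt]); n_r <- sum(lib[!tgt])
  p <- two_prop_pvalue(x_t, n_t, x_r, n_r)
  q <- bh_adjust(p)

  call <- rep("unchanged", nrow(counts))
  call[log2_fc > log2(fc_min) & q < fdr_max] <- "target_specific"
  call[log2_fc < -log2(fc_min) & q < fdr_max] <- "reference_specific"
  data.frame(peak_id = rownames(counts), mean_target = mean_t,
             mean_reference = mean_r, log2_fc = log2_fc,
             p_value = p, q_value = q, call = call, row.names = NULL)
}

# Vectorized chi-square two-proportion test with Yates continuity
# correction, matching prop.test(c(x1, x2), c(n1, n2), correct = TRUE).
two_prop_pvalue <- function(x1, n1, x2, n2) {
  phat <- (x1 + x2) / (n1 + n2)
  e11 <- n1 * phat; e21 <- n2 * phat
  e12 <- n1 - e11; e22 <- n2 - e21
  d <- abs(x1 - e11)
  yates <- pmin(0.5, d)
  stat <- (d - yates)^2 * (1 / e11 + 1 / e12 + 1 / e21 + 1 / e22)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[phat == 0 | phat == 1] <- 1   # degenerate margins carry no evidence
  p
}

#' One-sided Fisher exact p-value for motif enrichment
#'
#' Probability, under the null of equal hit rates, of observing at least
#' `n_target` hit peaks among `N_target` draws when `n_target + n_bg` of
#' the `N_target + N_bg` peaks carry a hit — the hypergeometric tail that
#' the one-sided Fisher exact test reports for enrichment.
#'
#' @param n_target,N_target Hit peaks and total peaks in the target set.
#' @param n_bg,N_bg Hit peaks and total peaks in the background set.
#' @return One-sided p-value in \[0, 1\].
#' @export
fisher_enrichment_p <- function(n_target, N_target, n_bg, N_bg) {
  if (any(n_target < 0 | n_target > N_target | n_bg < 0 | n_bg > N_bg))
    stopf("fisher_enrichment_p: need 0 <= n <= N on both sides")
  stats::phyper(n_target - 1, n_target + n_bg,
                N_target + N_bg - n_target - n_bg, N_target,
                lower.tail = FALSE)
}

#' Motif enrichment in target vs background peaks
#'
#' For every library motif: call per-window hits at the exact-p-value
#' threshold `hit_alpha`, reduce to ZOOPS per-peak presence, form the 2x2
#' table (peaks with/without a hit in target vs background) and test
#' enrichment with the one-sided Fisher exact test (hypergeometric tail).
#' Fold enrichment is the ratio of hit fractions with a 0.5 Haldane
#' correction to both hit counts when the background count is zero; q-values
#' are BH across motifs.
#'
#' @param motifs List of [pwm()] objects (a motif library).
#' @param target [peak_set()] of state-specific peaks, sequences attached.
#' @param background [peak_set()] of background peaks, sequences attached.
#' @param hit_alpha Per-window, per-strand hit-calling tail probability
#'   (default 1e-4).
#' @param background_freqs Base composition for the scanning null model;
#'   default uniform, or `"empirical"` to estimate mononucleotide
#'   frequencies from the background peak sequences.
#' @param scale Score discretization granularity (see [log_odds()]).
#' @return data.frame of class `enrichment_result`, sorted by p ascending
#'   (ties by motif id): `motif_id`, `tf_name`, `n_target`, `N_target`,
#'   `n_bg`, `N_bg`, `fold_enrichment`, `p_value`, `q_value`.
#' @export
motif_enrichment <- function(motifs, target, background, hit_alpha = 1e-4,
                             background_freqs = rep(0.25, 4), scale = 1000L) {
  stopifnot(inherits(target, "PeakSet"), inherits(background, "PeakSet"))
  if (length(motifs) == 0) stopf("motif_enrichment: empty motif library")
  if (length(target) == 0 || length(background) == 0)
    stopf("motif_enrichment: empty PeakSet")
  if (identical(background_freqs, "empirical"))
    background_freqs <- mono_freqs(background$sequences)
  check_freqs(background_freqs)
  max_w <- max(vapply(motifs, `[[`, 0L, "width"))
  enc_t <- encode_peak_set(target, max_width = max(40L, max_w))
  enc_b <- encode_peak_set(background, max_width = max(40L, max_w))
  rows <- lapply(motifs, function(p) {
    sm <- log_odds(p, background_freqs, scale = scale)
    thr <- suppressWarnings(threshold_for_pvalue(sm, hit_alpha))
    n_t <- sum(peak_hit_vector(sm, enc_t, thr$int_threshold))
    n_b <- sum(peak_hit_vector(sm, enc_b, thr$int_threshold))
    N_t <- enc_t$n_peaks; N_b <- enc_b$n_peaks
    pval <- fisher_enrichment_p(n_t, N_t, n_b, N_b)
    fold <- if (n_b == 0) ((n_t + 0.5) / N_t) / ((n_b + 0.5) / N_b)
            else (n_t / N_t) / (n_b / N_b)
    data.frame(motif_id = p$id, tf_name = p$tf_name, n_target = n_t,
               N_target = N_t, n_bg = n_b, N_bg = N_b,
               fold_enrichment = fold, p_value = pval)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$motif_id), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

mono_freqs <- function(seqs) {
  codes <- unlist(lapply(seqs, encode_seq), use.names = FALSE)
  tab <- tabulate(codes[codes <= 4], nbins = 4)
  tab / sum(tab)
}

#' Write an enrichment report TSV
#'
#' @param res [motif_enrichment()] result.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
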