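# Window scores for one strand: integer-encoded sequence codes (1..5, 5 = N),
# numeric lookup rows with -Inf for N so any window touching an N (or a
# padding symbol between concatenated peaks) scores -Inf and can never pass a
# finite threshold.
window_scores <- function(int_scores, codes) {
  W <- ncol(int_scores)
  n_win <- length(codes) - W + 1
  if (n_win < 1) return(numeric(0))
  total <- numeric(n_win)
  for (j in seq_len(W)) {
    lut <- c(int_scores[, j], -Inf)
    total <- total + lut[codes[j:(j + n_win - 1)]]
  }
  total
}

rc_int_scores <- function(int_scores) {
  m <- int_scores[c(4, 3, 2, 1), rev(seq_len(ncol(int_scores))), drop = FALSE]
  rownames(m) <- BASES
  m
}

#' Scan a sequence for motif hits
#'
#' Slides the scoring matrix over every window of the sequence and reports
#' those scoring at or above the threshold. Minus-strand hits are found with
#' the reverse-complement matrix and reported at the forward-strand offset
#' of the window start. Windows containing N are skipped.
#'
#' @param sm A [log_odds()] scoring matrix.
#' @param seq Nucleotide string over \{A,C,G,T,N\}.
#' @param threshold Real score threshold in bits (e.g. from
#'   [threshold_for_pvalue()]).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param peak_name Name recorded on each hit.
#' @return data.frame of hits: `peak_name`, `offset` (0-based, forward
#'   strand), `strand`, `score` (bits), `motif_id`.
#' @export
scan_sequence <- function(sm, seq, threshold, both_strands = TRUE,
                          peak_name = "seq") {
  stopifnot(inherits(sm, "ScoringMatrix"))
  codes <- encode_seq(seq)
  t_int <- round(threshold * sm$scale)
  hit_frames <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    m <- if (st == "+") sm$int_scores else rc_int_scores(sm$int_scores)
    sc <- window_scores(m, codes)
    idx <- which(sc >= t_int)
    if (length(idx))
      hit_frames[[st]] <- data.frame(
        peak_name = peak_name, offset = idx - 1L, strand = st,
        score = sc[idx] / sm$scale, motif_id = sm$pwm_id)
  }
  if (length(hit_frames) == 0)
    return(data.frame(peak_name = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      motif_id = character()))
  out <- do.call(rbind, hit_frames)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# Concatenate a PeakSet's sequences into one code vector with max_width - 1
# N symbols between peaks so no window spans two peaks. Returns codes plus
# the peak index of each window start. Encoded once, reused across motifs.
encode_peak_set <- function(peaks, max_width = 40L) {
  if (is.null(peaks$sequences))
    stopf("PeakSet '%s' has no sequences attached", peaks$label)
  seqs <- peaks$sequences
  gap <- max_width - 1L
  lens <- nchar(seqs)
  codes <- integer(sum(lens) + gap * length(seqs))
  peak_of <- integer(length(codes))
  pos <- 0L
  for (i in seq_along(seqs)) {
    codes[(pos + 1):(pos + lens[i])] <- encode_seq(seqs[[i]])
    peak_of[(pos + 1):(pos + lens[i])] <- i
    pos <- pos + lens[i]
    if (gap > 0) {
      codes[(pos + 1):(pos + gap)] <- 5L
      pos <- pos + gap
    }
  }
  list(codes = codes, peak_of = peak_of, n_peaks = length(seqs),
       peak_names = names(seqs))
}

# Logical vector: does peak i contain >= 1 hit on either strand?
peak_hit_vector <- function(sm, enc, t_int, both_strands = TRUE) {
  hit <- logical(enc$n_peaks)
  strands <- if (both_strands) 1:2 else 1
  for (st in strands) {
    m <- if (st == 1) sm$int_scores else rc_int_scores(sm$int_scores)
    sc <- window_scores(m, enc$codes)
    idx <- which(sc >= t_int)
    if (length(idx)) hit[unique(enc$peak_of[idx])] <- TRUE
  }
  hit
}

#' Count peaks containing a motif hit (ZOOPS)
#'
#' Reduces all hits to per-peak presence/absence — the zero-or-one
#' occurrence per sequence (ZOOPS) statistic feeding the enrichment test.
#'
#' @param sm A [log_odds()] scoring matrix.
#' @param peaks A [peak_set()] with sequences attached.
#' @param threshold Real score threshold in bits.
#' @param both_strands Scan both strands (default TRUE).
#' @return `c(n_hit = <peaks with a hit>, N = <total peaks>)`.
#' @export
peaks_with_hit <- function(sm, peaks, threshold, both_strands = TRUE) {
  stopifnot(inherits(sm, "ScoringMatrix"), inherits(peaks, "PeakSet"))
  enc <- encode_peak_set(peaks, max_width = max(40L, sm$width))
  hit <- peak_hit_vector(sm, enc, round(threshold * sm$scale), both_strands)
  c(n_hit = sum(hit), N = enc$n_peaks)
}

#' Count total motif occurrences per peak
#'
#' Total-occurrence alternative to the default ZOOPS reduction; overlapping
#' and double-strand occurrences each count.
#'
#' @inheritParams peaks_with_hit
#' @return Named integer vector of occurrence counts, one per peak.
#' @export
peak_hit_counts <- function(sm, peaks, threshold, both_strands = TRUE) {
  stopifnot(inherits(sm, "ScoringMatrix"), inherits(peaks, "PeakSet"))
  enc <- encode_peak_set(peaks, max_width = max(40L, sm$width))
  t_int <- round(threshold * sm$scale)
  counts <- integer(enc$n_peaks)
  strands <- if (both_strands) 1:2 else 1
  for (st in strands) {
    m <- if (st == 1) sm$int_scores else rc_int_scores(sm$int_scores)
    sc <- window_scores(m, enc$codes)
    idx <- which(sc >= t_int)
    if (length(idx)) {
      tab <- table(enc$peak_of[idx])
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] + as.integer(tab)
    }
  }
  stats::setNames(counts, enc$peak_names)
}
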