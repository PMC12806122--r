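#' Position weight matrices
#'
#' A `Pwm` is a per-position base-probability model of a transcription
#' factor's binding preference. Columns are motif positions, rows are the
#' bases A, C, G, T; every column sums to 1 and, because parsers apply a
#' pseudocount, every probability is strictly positive.
#'
#' @param id Motif identifier (unique within a library).
#' @param prob 4 x W numeric matrix of base probabilities, rows in A,C,G,T
#'   order (rownames optional; enforced on construction).
#' @param tf_name Transcription factor name; defaults to `id`.
#' @param family Optional TF family annotation.
#' @param source_dialect Where the matrix came from ("jaspar", "homer",
#'   "manual", ...).
#' @return An object of class `Pwm`.
#' @examples
#' m <- matrix(c(.85, .05, .05, .05), 4, 6)
#' p <- pwm("toyA", m)
#' consensus_site(p)
#' @export
pwm <- function(id, prob, tf_name = id, family = NULL, source_dialect = "manual") {
  if (!is.matrix(prob) || nrow(prob) != 4)
    stopf("pwm '%s': prob must be a 4 x W matrix (rows A,C,G,T)", id)
  W <- ncol(prob)
  if (W < 4) stopf("pwm '%s': width %d < 4", id, W)
  if (any(!is.finite(prob)) || any(prob <= 0))
    stopf("pwm '%s': all probabilities must be strictly positive", id)
  csums <- colSums(prob)
  if (any(abs(csums - 1) > 1e-6))
    stopf("pwm '%s': column(s) %s do not sum to 1",
          id, paste(which(abs(csums - 1) > 1e-6), collapse = ","))
  dimnames(prob) <- list(BASES, NULL)
  structure(
    list(id = id, tf_name = tf_name, family = family,
         width = W, prob = prob, source_dialect = source_dialect),
    class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm %s (%s), width %d, source %s\n  consensus: %s\n",
              x$id, x$tf_name, x$width, x$source_dialect, consensus_site(x)))
  invisible(x)
}

#' Reverse-complement a PWM
#'
#' Reverses the column order and swaps complementary base rows (A with T,
#' C with G), giving the binding model of the same factor read on the
#' opposite strand. Applying it twice returns the original matrix.
#'
#' @param x A [pwm()].
#' @return A `Pwm` with id suffixed `"_rc"` (double application restores the
#'   original id).
#' @export
reverse_complement <- function(x) {
  stopifnot(inherits(x, "Pwm"))
  prob <- x$prob[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(prob) <- BASES
  new_id <- if (endsWith(x$id, "_rc")) sub("_rc$", "", x$id) else paste0(x$id, "_rc")
  pwm(new_id, prob, tf_name = x$tf_name, family = x$family,
      source_dialect = x$source_dialect)
}

# IUPAC code for each non-empty subset of {A,C,G,T}
IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Consensus binding site of a PWM
#'
#' `strict` mode returns the most probable base at every column (ties broken
#' in fixed A < C < G < T order), i.e. the single sequence used as the
#' repeated unit when assembling tandem-array promoters. `iupac` mode
#' returns the smallest degenerate code covering every base with
#' probability >= 0.25 at each column.
#'
#' @param x A [pwm()].
#' @param mode `"strict"` or `"iupac"`.
#' @return A nucleotide string of length `width(x)`.
#' @export
consensus_site <- function(x, mode = c("strict", "iupac")) {
  stopifnot(inherits(x, "Pwm"))
  mode <- match.arg(mode)
  if (mode == "strict") {
    paste(BASES[apply(x$prob, 2, which.max)], collapse = "")
  } else {
    codes <- apply(x$prob, 2, function(col) {
      bases <- BASES[col >= 0.25]
      if (length(bases) == 0) bases <- BASES[which.max(col)]
      IUPAC[[paste(bases, collapse = "")]]
    })
    paste(codes, collapse = "")
  }
}

#' Log-odds scoring matrix
#'
#' Converts base probabilities into additive per-position scores
#' `log2(prob / background)` (bits), together with an integer-discretized
#' copy (`round(score * scale)`) used for exact score-distribution
#' arithmetic and fast scanning.
#'
#' @param x A [pwm()].
#' @param background 4 base frequencies (A,C,G,T order), strictly positive.
#' @param scale Integer discretization granularity; default 1000 gives
#'   0.001-bit resolution.
#' @return An object of class `ScoringMatrix` with elements `pwm_id`,
#'   `width`, `scores` (4 x W, bits), `background`, `scale`, `int_scores`.
#' @export
log_odds <- function(x, background = rep(0.25, 4), scale = 1000L) {
  stopifnot(inherits(x, "Pwm"))
  check_freqs(background)
  if (any(background <= 0))
    stopf("log_odds: zero background frequency for base %s",
          paste(BASES[background <= 0], collapse = ","))
  scores <- log2(x$prob / background)
  structure(
    list(pwm_id = x$id, width = x$width, scores = scores,
         background = background, scale = as.integer(scale),
         int_scores = round(scores * scale)),
    class = "ScoringMatrix")
}

#' @export
print.ScoringMatrix <- function(x, ...) {
  cat(sprintf("ScoringMatrix for %s: width %d, scale %d, max score %.3f bits\n",
              x$pwm_id, x$width, x$scale, sum(apply(x$scores, 2, max))))
  invisible(x)
}

#' Exact null distribution of the motif score
#'
#' Distribution of the total integer score of a random W-mer whose bases are
#' drawn independently from the scoring matrix's background, computed by
#' column-wise convolution. This is the exact reference distribution used to
#' convert a tail probability into a score threshold.
#'
#' @param sm A [log_odds()] scoring matrix.
#' @param max_support Resource guard on the distribution's integer support
#'   size; exceeding it raises an error suggesting a coarser `scale`.
#' @return A list with `score` (integer support, ascending) and `prob`
#'   (probabilities summing to 1 within 1e-9).
#' @export
score_distribution <- function(sm, max_support = 1e7) {
  stopifnot(inherits(sm, "ScoringMatrix"))
  ints <- sm$int_scores
  lo <- sum(apply(ints, 2, min)); hi <- sum(apply(ints, 2, max))
  if (hi - lo + 1 > max_support)
    stopf(paste("score_distribution: support size %d exceeds max_support %g;",
                "use a coarser discretization scale"), hi - lo + 1, max_support)
  bg <- sm$background
  # dense convolution over columns; probs[i] = P(score == offset + i - 1)
  probs <- 1; offset <- 0
  for (j in seq_len(sm$width)) {
    v <- ints[, j]
    cmin <- min(v); cmax <- max(v)
    acc <- numeric(length(probs) + (cmax - cmin))
    for (b in 1:4) {
      sh <- v[b] - cmin
      idx <- seq_along(probs) + sh
      acc[idx] <- acc[idx] + probs * bg[b]
    }
    probs <- acc; offset <- offset + cmin
  }
  keep <- probs > 0
  list(score = offset + which(keep) - 1L, prob = probs[keep])
}

#' Score threshold attaining a tail p-value
#'
#' Smallest score t with `P(score >= t) <= alpha` under the exact background
#' score distribution, i.e. the per-window hit-calling threshold for a given
#' false-positive rate per scanned position and strand.
#'
#' @param sm A [log_odds()] scoring matrix.
#' @param alpha Tail probability in (0, 1).
#' @return A list: `threshold` (real scale, bits), `int_threshold`,
#'   `achieved_alpha` (exact tail probability at the threshold), and
#'   `unattainable` (TRUE when even the maximum score has tail > alpha; the
#'   maximum score is returned with achieved tail reported as 0).
#' @export
threshold_for_pvalue <- function(sm, alpha) {
  stopifnot(inherits(sm, "ScoringMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stopf("threshold_for_pvalue: alpha must be in (0, 1]")
  d <- score_distribution(sm)
  tail <- rev(cumsum(rev(d$prob)))
  ok <- which(tail <= alpha)
  if (length(ok) == 0) {
    t_int <- max(d$score)
    warning(sprintf("no score of %s attains tail <= %g; returning max score",
                    sm$pwm_id, alpha))
    return(list(threshold = t_int / sm$scale, int_threshold = t_int,
                achieved_alpha = 0, unattainable = TRUE))
  }
  i <- ok[1]
  list(threshold = d$score[i] / sm$scale, int_threshold = d$score[i],
       achieved_alpha = tail[i], unattainable = FALSE)
}
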