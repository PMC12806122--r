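#' Simulation configuration
#'
#' Conditions for a synthetic multi-dataset study: K datasets, each a pair
#' of target and background peak sets drawn from an i.i.d. mononucleotide
#' background, with motif instances planted into target (and, at a lower
#' rate, background) peaks. Defaults emulate a desk-scale version of a
#' multi-model chromatin-state comparison: 3 datasets, 200 peaks per side,
#' 200 bp peaks, planting probability 0.6 in target vs 0.05 in background.
#'
#' @param n_peaks_target,n_peaks_background Peaks per set (default 200).
#' @param peak_len Peak length in bp (default 200).
#' @param background_freqs Base frequencies (A,C,G,T), default uniform.
#' @param plant_prob_target Per-peak planting probability in target peaks
#'   (default 0.6).
#' @param plant_prob_background Per-peak planting probability in background
#'   peaks (default 0.05).
#' @param k_datasets Number of datasets (default 3).
#' @param seed Master seed; dataset d uses `seed + d`.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(n_peaks_target = 200L, n_peaks_background = 200L,
                       peak_len = 200L, background_freqs = rep(0.25, 4),
                       plant_prob_target = 0.6, plant_prob_background = 0.05,
                       k_datasets = 3L, seed = 1L) {
  check_freqs(background_freqs)
  for (p in c(plant_prob_target, plant_prob_background))
    if (p < 0 || p > 1) stopf("sim_config: planting probabilities must be in [0, 1]")
  if (n_peaks_target < 1 || n_peaks_background < 1 || peak_len < 1)
    stopf("sim_config: peak counts and length must be >= 1")
  structure(list(n_peaks_target = as.integer(n_peaks_target),
                 n_peaks_background = as.integer(n_peaks_background),
                 peak_len = as.integer(peak_len),
                 background_freqs = background_freqs,
                 plant_prob_target = plant_prob_target,
                 plant_prob_background = plant_prob_background,
                 k_datasets = as.integer(k_datasets),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate background peak sequences
#'
#' Draws `n` sequences of the given length with bases i.i.d. from `freqs`
#' (order-0 Markov background). Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param n Number of peaks.
#' @param length Peak length (bp).
#' @param freqs Base frequencies (A,C,G,T).
#' @param seed Integer seed.
#' @param label PeakSet label (also used as the synthetic chrom name).
#' @return A [peak_set()] with sequences attached.
#' @export
simulate_background <- function(n, length, freqs = rep(0.25, 4), seed = 1L,
                                label = "sim") {
  check_freqs(freqs)
  if (length < 1) stopf("simulate_background: length must be >= 1")
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(BASES, length, replace = TRUE, prob = freqs), collapse = ""),
    ""))
  ends <- seq_len(n) * length
  peak_set(data.frame(chrom = label, start = ends - length, end = ends,
                      name = sprintf("%s_peak_%d", label, seq_len(n))),
           label = label, sequences = seqs)
}

#' Plant motif instances into peaks
#'
#' Each peak is independently selected with probability `prob`; in a
#' selected peak one W-mer is sampled column-wise from the PWM, reverse
#' complemented on a uniformly chosen strand, and written over the sequence
#' at a uniformly chosen offset. Truth records carry the planted word as it
#' appears on the forward strand at the recorded offset.
#'
#' @param peaks A [peak_set()] with sequences.
#' @param pwm_obj The [pwm()] to plant.
#' @param prob Per-peak planting probability in \[0, 1\].
#' @param seed Integer seed.
#' @return List: `peaks` (modified set) and `truth` (data.frame `peak`,
#'   `offset` 0-based, `strand`, `word` forward-strand, `motif_id`).
#' @export
plant_motifs <- function(peaks, pwm_obj, prob, seed = 1L) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(pwm_obj, "Pwm"))
  if (is.null(peaks$sequences)) stopf("plant_motifs: peaks need sequences")
  W <- pwm_obj$width
  lens <- nchar(peaks$sequences)
  if (any(lens < W))
    stopf("plant_motifs: peak '%s' (%d bp) shorter than motif width %d",
          peaks$intervals$name[which(lens < W)[1]], min(lens), W)
  empty_truth <- data.frame(peak = character(), offset = integer(),
                            strand = character(), word = character(),
                            motif_id = character())
  if (prob == 0) return(list(peaks = peaks, truth = empty_truth))
  res <- with_seed(seed, {
    seqs <- peaks$sequences
    sel <- which(stats::runif(length(seqs)) < prob)
    truth <- lapply(sel, function(i) {
      word <- paste(vapply(seq_len(W), function(j)
        sample(BASES, 1, prob = pwm_obj$prob[, j]), ""), collapse = "")
      strand <- sample(c("+", "-"), 1)
      fwd_word <- if (strand == "+") word else revcomp_seq(word)
      off <- sample.int(lens[i] - W + 1, 1) - 1L
      substr(seqs[i], off + 1, off + W) <<- fwd_word
      data.frame(peak = peaks$intervals$name[i], offset = off, strand = strand,
                 word = fwd_word, motif_id = pwm_obj$id)
    })
    list(seqs = seqs,
         truth = if (length(truth)) do.call(rbind, truth) else empty_truth)
  })
  list(peaks = peak_set(peaks$intervals, label = peaks$label,
                        sequences = unname(res$seqs)),
       truth = res$truth)
}

#' Random high-information PWM
#'
#' Generates a motif with one dominant base per column (probability
#' `dominance`, remainder split evenly) — a convenient stand-in for a
#' sharply defined TF binding preference in simulations and tests.
#'
#' @param id Motif id.
#' @param width Motif width (default 8).
#' @param seed Integer seed.
#' @param dominance Probability of the consensus base per column
#'   (default 0.9).
#' @return A [pwm()].
#' @export
random_pwm <- function(id, width = 8L, seed = 1L, dominance = 0.9) {
  if (dominance <= 0.25 || dominance >= 1)
    stopf("random_pwm: dominance must be in (0.25, 1)")
  cons <- with_seed(seed, sample.int(4, width, replace = TRUE))
  prob <- matrix((1 - dominance) / 3, 4, width)
  prob[cbind(cons, seq_len(width))] <- dominance
  pwm(id, prob, source_dialect = "simulated")
}

#' Simulate a K-dataset study with planted truth
#'
#' Builds `cfg$k_datasets` pairs of target/background peak sets. Motifs in
#' `shared` are planted into every dataset's target peaks at
#' `plant_prob_target`; each entry of `private` (a list of motif-id vectors,
#' one per dataset) is planted only into its own dataset. All planted
#' motifs also appear in background peaks at `plant_prob_background`.
#' Optionally builds a two-condition [count_matrix()] in which
#' target-specific peaks carry `count_fc`-fold higher counts; the matrix
#' also contains nine state-invariant filler peaks per target peak so that,
#' as in real peak atlases, differential peaks are a minority and
#' library-size normalization does not absorb the fold change.
#'
#' @param cfg A [sim_config()].
#' @param library Named list of [pwm()] objects.
#' @param shared Motif ids planted in all datasets (default: all).
#' @param private List (length `k_datasets`) of motif-id vectors planted in
#'   one dataset each; default none.
#' @param with_counts Also simulate a count matrix (default FALSE).
#' @param count_fc Fold change of target-specific peak counts (default 4).
#' @param count_base Mean reference count per peak (default 50).
#' @param n_reps Samples per condition in the count matrix (default 2).
#' @return List of class `SimStudy`: `datasets` (list of `list(target,
#'   background)`), `truth` (data.frame with a `dataset` column), `counts`
#'   (per-dataset list of [count_matrix()] or NULL), `cfg`.
#' @export
simulate_study <- function(cfg, library, shared = names(library),
                           private = NULL, with_counts = FALSE,
                           count_fc = 4, count_base = 50, n_reps = 2L) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (length(library) == 0) stopf("simulate_study: empty motif library")
  if (is.null(names(library)))
    names(library) <- vapply(library, `[[`, "", "id")
  K <- cfg$k_datasets
  if (is.null(private)) private <- rep(list(character(0)), K)
  if (length(private) != K)
    stopf("simulate_study: private must list motif ids for each of %d datasets", K)
  missing <- setdiff(c(shared, unlist(private)), names(library))
  if (length(missing))
    stopf("simulate_study: motif(s) %s not in library", paste(missing, collapse = ","))

  datasets <- vector("list", K)
  truths <- list()
  counts <- vector("list", K)
  for (d in seq_len(K)) {
    sd <- cfg$seed + d
    tgt <- simulate_background(cfg$n_peaks_target, cfg$peak_len,
                               cfg$background_freqs, seed = sd * 1000 + 1,
                               label = sprintf("ds%d_target", d))
    bg <- simulate_background(cfg$n_peaks_background, cfg$peak_len,
                              cfg$background_freqs, seed = sd * 1000 + 2,
                              label = sprintf("ds%d_background", d))
    ids <- c(shared, private[[d]])
    for (m in seq_along(ids)) {
      p <- library[[ids[m]]]
      pt <- plant_motifs(tgt, p, cfg$plant_prob_target,
                         seed = sd * 1000 + 100 + m)
      tgt <- pt$peaks
      pb <- plant_motifs(bg, p, cfg$plant_prob_background,
                         seed = sd * 1000 + 500 + m)
      bg <- pb$peaks
      for (tr in list(pt$truth, pb$truth)) if (nrow(tr)) {
        tr$dataset <- d
        truths[[length(truths) + 1]] <- tr
      }
    }
    datasets[[d]] <- list(target = tgt, background = bg)
    if (with_counts)
      counts[[d]] <- simulate_counts(tgt, bg, count_fc, count_base, n_reps,
                                     seed = sd * 1000 + 900)
  }
  structure(list(datasets = datasets,
                 truth = if (length(truths)) do.call(rbind, truths)
                         else data.frame(),
                 counts = if (with_counts) counts else NULL,
                 cfg = cfg),
            class = "SimStudy")
}

# Count matrix over target + background peaks plus unchanged filler peaks:
# target-state samples see fc-fold higher counts on the target peaks, flat
# counts elsewhere. The filler emulates the bulk of a peak atlas where most
# regions are state-invariant; without it, library-size normalization would
# absorb much of the planted fold change (composition bias).
simulate_counts <- function(target, background, fc, base, n_reps, seed,
                            unchanged_per_diff = 9L) {
  n_fill <- unchanged_per_diff * length(target)
  ids <- c(target$intervals$name, background$intervals$name,
           sprintf("unchanged_%d", seq_len(n_fill)))
  is_tgt <- c(rep(TRUE, length(target)),
              rep(FALSE, length(background) + n_fill))
  with_seed(seed, {
    cols <- list()
    for (r in seq_len(n_reps))
      cols[[sprintf("target_%d", r)]] <-
        stats::rpois(length(ids), ifelse(is_tgt, base * fc, base))
    for (r in seq_len(n_reps))
      cols[[sprintf("reference_%d", r)]] <- stats::rpois(length(ids), base)
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    count_matrix(m, stats::setNames(
      rep(c("target", "reference"), each = n_reps), colnames(m)))
  })
}

#' Export a simulated study to standard files
#'
#' Writes per-dataset BED + FASTA for target and background peaks, a truth
#' TSV, and (when present) count-matrix TSVs, all under `dir`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "SimStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_along(study$datasets)) {
    for (side in c("target", "background")) {
      ps <- study$datasets[[d]][[side]]
      write_bed(ps, file.path(dir, sprintf("ds%d_%s.bed", d, side)))
      write_peak_fasta(ps, file.path(dir, sprintf("ds%d_%s.fa", d, side)))
    }
    if (!is.null(study$counts))
      write_count_matrix(study$counts[[d]],
                         file.path(dir, sprintf("ds%d_counts.tsv", d)),
                         file.path(dir, sprintf("ds%d_conditions.tsv", d)))
  }
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
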