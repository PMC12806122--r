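#' Peak sets
#'
#' A `PeakSet` bundles named genomic intervals (0-based half-open, the BED
#' convention) with optional per-interval nucleotide sequences. It is the
#' unit of chromatin-state evidence: one set of state-specific accessible
#' regions.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`
#'   and optionally `score`. Starts are 0-based inclusive, ends exclusive.
#' @param label Name for the set (e.g. "exhausted_target").
#' @param sequences Optional character vector of sequences over
#'   \{A,C,G,T,N\}, one per interval, each of length `end - start`.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(intervals, label = "peaks", sequences = NULL) {
  need <- c("chrom", "start", "end", "name")
  if (!is.data.frame(intervals) || !all(need %in% names(intervals)))
    stopf("peak_set: intervals must have columns %s", paste(need, collapse = ", "))
  if (nrow(intervals) > 0) {
    if (any(intervals$chrom == "" | is.na(intervals$chrom)))
      stopf("peak_set: empty chrom")
    bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
    if (length(bad))
      stopf("peak_set: interval %d violates 0 <= start < end", bad[1])
    if (anyDuplicated(intervals$name))
      stopf("peak_set: duplicate interval name '%s'",
            intervals$name[duplicated(intervals$name)][1])
  }
  if (!is.null(sequences)) {
    if (length(sequences) != nrow(intervals))
      stopf("peak_set: %d sequences for %d intervals",
            length(sequences), nrow(intervals))
    lens <- nchar(sequences)
    bad <- which(lens != intervals$end - intervals$start)
    if (length(bad))
      stopf("peak_set: sequence length %d != interval width %d for '%s'",
            lens[bad[1]], intervals$end[bad[1]] - intervals$start[bad[1]],
            intervals$name[bad[1]])
    names(sequences) <- intervals$name
  }
  rownames(intervals) <- NULL
  structure(list(label = label, intervals = intervals, sequences = sequences),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals%s\n", x$label, nrow(x$intervals),
              if (is.null(x$sequences)) "" else " (sequences attached)"))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$intervals)

#' Read a BED3/BED4 file into a PeakSet
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Intervals
#' missing a name field are auto-named `peak_<index>`.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @param label Label for the resulting set; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stopf("read_bed: no such file '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), name = character()),
                    label = label))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("read_bed: line %d has %d fields (need >= 3)", i, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stopf("read_bed: line %d has non-integer coordinates", i)
    if (start < 0 || start >= end)
      stopf("read_bed: line %d violates 0 <= start < end (%d, %d)", i, start, end)
    list(chrom = f[1], start = start, end = end,
         name = if (length(f) >= 4 && nzchar(f[4])) f[4] else sprintf("peak_%d", i),
         score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_)
  })
  peak_set(data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    name = vapply(rows, `[[`, "", "name"),
    score = vapply(rows, `[[`, 0, "score")), label = label)
}

#' Write a PeakSet as BED
#'
#' @param peaks A [peak_set()].
#' @param path Output path; BED4 (plus score column when any score is set).
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  iv <- peaks$intervals
  cols <- c("chrom", "start", "end", "name")
  if (!is.null(iv$score) && any(!is.na(iv$score))) {
    iv$score[is.na(iv$score)] <- 0
    cols <- c(cols, "score")
  }
  utils::write.table(iv[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach genomic sequences to a PeakSet
#'
#' Extracts each interval's sequence from a genome source, uppercases it and
#' maps any non-ACGT character to N.
#'
#' @param peaks A [peak_set()].
#' @param genome A named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @return The PeakSet with `sequences` populated.
#' @export
attach_sequences <- function(peaks, genome) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
    # FASTA headers may carry descriptions; key on the first word
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, "", 1)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stopf("attach_sequences: genome sequences must be named by chromosome")
  iv <- peaks$intervals
  seqs <- vapply(seq_len(nrow(iv)), function(i) {
    chrom <- iv$chrom[i]
    if (!chrom %in% names(genome))
      stopf("attach_sequences: chrom '%s' (interval '%s') not in genome",
            chrom, iv$name[i])
    if (iv$end[i] > nchar(genome[[chrom]]))
      stopf("attach_sequences: interval '%s' (end %d) exceeds %s length %d",
            iv$name[i], iv$end[i], chrom, nchar(genome[[chrom]]))
    substr(genome[[chrom]], iv$start[i] + 1, iv$end[i])
  }, "")
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  peak_set(iv, label = peaks$label, sequences = seqs)
}

#' Write PeakSet sequences as FASTA
#'
#' @param peaks A [peak_set()] with sequences attached.
#' @param path Output FASTA path.
#' @export
write_peak_fasta <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.null(peaks$sequences))
    stopf("write_peak_fasta: '%s' has no sequences attached", peaks$label)
  x <- Biostrings::DNAStringSet(peaks$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read peak sequences from FASTA
#'
#' Builds a PeakSet whose intervals are synthetic (`chrom = label`, laid out
#' end to end) and whose sequences come from the file; the inverse of
#' [write_peak_fasta()] up to coordinates.
#'
#' @param path FASTA path.
#' @param label Label for the set.
#' @return A [peak_set()] with sequences attached.
#' @export
read_peak_fasta <- function(path, label = basename(path)) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGT]", "N", seqs)
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  nm <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1)
  peak_set(data.frame(chrom = label, start = ends - lens, end = ends, name = nm),
           label = label, sequences = unname(seqs))
}
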