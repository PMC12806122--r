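#' Read a motif library (JASPAR PFM or Homer format)
#'
#' JASPAR files hold count blocks: a `>ID NAME` header followed by four rows
#' (optionally prefixed `A [ ... ]` etc.) of per-position counts, which are
#' converted to probabilities as `(count + pseudocount) / (colsum + 4 *
#' pseudocount)`. Homer files hold a `>consensus name threshold` header
#' followed by one row of four base probabilities per position; these are
#' renormalized but not pseudocounted (a 1e-6 floor is applied only when a
#' row contains an exact zero, since PWM probabilities must stay positive).
#'
#' Motif ids duplicated within or across files can be disambiguated with
#' [unique_motif_ids()]; this reader suffixes duplicates within one file.
#'
#' @param path Motif file path.
#' @param dialect `"jaspar"` or `"homer"`.
#' @param pseudocount Count added per base before normalization (JASPAR
#'   dialect); default 1.
#' @return A named list of [pwm()] objects.
#' @export
read_motifs <- function(path, dialect = c("jaspar", "homer"), pseudocount = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("read_motifs: no such file '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "jaspar") pwms <- parse_jaspar(lines, pseudocount, path)
  else pwms <- parse_homer(lines, path)
  unique_motif_ids(pwms)
}

parse_numeric_row <- function(line, path) {
  # accepts "A [ 1 2 3 ]" / "1 2 3" / tab or space separated
  row <- gsub("^\\s*[ACGTacgt]\\s*\\[", "", line)
  row <- gsub("\\]\\s*$", "", row)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(row), "[ \t]+")[[1]]))
  if (any(is.na(vals))) stopf("read_motifs (%s): non-numeric row '%s'", path, line)
  if (any(vals < 0)) stopf("read_motifs (%s): negative entry in row '%s'", path, line)
  vals
}

parse_jaspar <- function(lines, pseudocount, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stopf("read_motifs (%s): no '>' headers found", path)
  bounds <- c(hdr, length(lines) + 1)
  lapply(seq_along(hdr), function(k) {
    block <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    if (length(block) != 4)
      stopf("read_motifs (%s): motif block %d has %d rows (need 4)",
            path, k, length(block))
    mat <- do.call(rbind, lapply(block, parse_numeric_row, path = path))
    if (ncol(mat) < 4)
      stopf("read_motifs (%s): motif block %d is only %d columns wide",
            path, k, ncol(mat))
    tot <- colSums(mat) + 4 * pseudocount
    if (any(tot <= 0))
      stopf("read_motifs (%s): zero-sum column in motif block %d with pseudocount %g",
            path, k, pseudocount)
    prob <- sweep(mat + pseudocount, 2, tot, "/")
    h <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "[ \t]+")[[1]]
    id <- h[1]
    pwm(id, prob, tf_name = if (length(h) >= 2) h[2] else id,
        source_dialect = "jaspar")
  })
}

parse_homer <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stopf("read_motifs (%s): no '>' headers found", path)
  bounds <- c(hdr, length(lines) + 1)
  lapply(seq_along(hdr), function(k) {
    block <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    rows <- lapply(block, parse_numeric_row, path = path)
    bad <- which(lengths(rows) != 4)
    if (length(bad))
      stopf("read_motifs (%s): motif %d row %d has %d values (need 4)",
            path, k, bad[1], length(rows[[bad[1]]]))
    mat <- t(do.call(rbind, rows))          # 4 x W
    if (ncol(mat) < 4)
      stopf("read_motifs (%s): motif %d is only %d positions wide", path, k, ncol(mat))
    tot <- colSums(mat)
    if (any(tot <= 0))
      stopf("read_motifs (%s): zero-sum position in motif %d", path, k)
    if (any(mat == 0)) mat <- mat + 1e-6
    prob <- sweep(mat, 2, colSums(mat), "/")
    h <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "[ \t]+")[[1]]
    id <- if (length(h) >= 2) h[2] else h[1]
    # Homer names often look like "BATF(bZIP)/...": keep the part before '('
    tf <- sub("[(/].*$", "", id)
    pwm(id, prob, tf_name = tf, source_dialect = "homer")
  })
}

#' Make motif ids unique across merged libraries
#'
#' Duplicate ids (e.g. after merging mouse and human libraries) are suffixed
#' `_2`, `_3`, ... in encounter order rather than rejected.
#'
#' @param pwms List of [pwm()] objects.
#' @return The list, named by (possibly suffixed) motif id.
#' @export
unique_motif_ids <- function(pwms) {
  ids <- vapply(pwms, `[[`, "", "id")
  counts <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    n <- counts[[id]]
    if (is.null(n)) counts[[id]] <- 1L
    else {
      counts[[id]] <- n + 1L
      pwms[[i]]$id <- sprintf("%s_%d", id, n + 1L)
    }
  }
  stats::setNames(pwms, vapply(pwms, `[[`, "", "id"))
}

#' Write PWMs in JASPAR dialect
#'
#' Writes each probability column scaled to a depth of 1e6 counts in the
#' standard `A [ ... ]` row layout, at full precision. Re-reading with
#' `pseudocount = 0` reproduces the probabilities exactly (normalization
#' divides by the written column sum), and the default pseudocount of 1
#' perturbs them only at the 1e-6 level, so written libraries can feed the
#' pipeline again without distortion.
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @export
write_motifs_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    stopifnot(inherits(p, "Pwm"))
    writeLines(sprintf(">%s %s", p$id, p$tf_name), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", BASES[b],
                         paste(formatC(p$prob[b, ] * 1e6, format = "g",
                                       digits = 17), collapse = " ")), con)
  }
  invisible(path)
}
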