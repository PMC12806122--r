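#' Write a promoter design as an annotated GenBank record
#'
#' One `misc_binding` feature per binding-site repeat (label
#' `"<TF>_site_<i>"`), one `misc_feature` per spacer (`"spacer_<i>"`), and a
#' `promoter` feature for the core promoter. Feature coordinates are
#' GenBank-style 1-based inclusive, converted from the design's internal
#' 0-based half-open layout at serialization time only.
#'
#' @param design A [build_promoter()] result with at least one repeat.
#' @param path Output path.
#' @export
write_genbank <- function(design, path) {
  stopifnot(inherits(design, "PromoterDesign"))
  if (design$repeats < 1 || !nzchar(design$full_seq))
    stopf("write_genbank: refusing to write an empty design (0 repeats)")
  seq <- design$full_seq
  con <- file(path, "w")
  on.exit(close(con))
  locus <- gsub("[^A-Za-z0-9_.-]", "_", sprintf("%s_x%d", design$tf_name,
                                                design$repeats))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN",
                     substr(locus, 1, 16), nchar(seq)), con)
  writeLines(sprintf("DEFINITION  synthetic promoter: %d x %s site, %s core.",
                     design$repeats, design$tf_name, design$core_promoter_name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  lay <- design$layout
  site_i <- 0; spacer_i <- 0
  for (i in seq_len(nrow(lay))) {
    from <- lay$start[i] + 1; to <- lay$end[i]      # to 1-based inclusive
    if (lay$type[i] == "site") {
      site_i <- site_i + 1
      key <- "misc_binding"; label <- sprintf("%s_site_%d", design$tf_name, site_i)
    } else if (lay$type[i] == "spacer") {
      spacer_i <- spacer_i + 1
      key <- "misc_feature"; label <- sprintf("spacer_%d", spacer_i)
    } else {
      key <- "promoter"; label <- design$core_promoter_name
    }
    writeLines(sprintf("     %-16s%d..%d", key, from, to), con)
    writeLines(sprintf("                     /label=\"%s\"", label), con)
    if (lay$type[i] == "site")
      writeLines(sprintf("                     /bound_moiety=\"%s\"", design$tf_name), con)
  }
  writeLines("ORIGIN", con)
  low <- tolower(seq)
  for (off in seq(1, nchar(seq), by = 60)) {
    chunk <- substr(low, off, min(off + 59, nchar(seq)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read back a GenBank record written by this package
#'
#' A minimal flat-file reader covering the subset [write_genbank()] emits;
#' used to verify designs on their serialized form (coordinates are
#' converted back to 0-based half-open).
#'
#' @param path GenBank file path.
#' @return List with `sequence` (uppercase) and `features` (data.frame:
#'   `key`, `start` 0-based, `end` exclusive, `label`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  feat_start <- grep("^FEATURES", lines)[1]
  orig_start <- grep("^ORIGIN", lines)[1]
  if (is.na(feat_start) || is.na(orig_start))
    stopf("read_genbank: '%s' lacks FEATURES/ORIGIN sections", path)
  keys <- character(); froms <- integer(); tos <- integer(); labels <- character()
  for (ln in lines[(feat_start + 1):(orig_start - 1)]) {
    m <- regmatches(ln, regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", ln))[[1]]
    if (length(m)) {
      keys <- c(keys, m[2]); froms <- c(froms, as.integer(m[3]))
      tos <- c(tos, as.integer(m[4])); labels <- c(labels, NA_character_)
    } else {
      lm <- regmatches(ln, regexec("/label=\"([^\"]*)\"", ln))[[1]]
      if (length(lm) && length(labels)) labels[length(labels)] <- lm[2]
    }
  }
  seq_lines <- lines[(orig_start + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(sequence = seq,
       features = data.frame(key = keys, start = froms - 1L, end = tos,
                             label = labels))
}
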