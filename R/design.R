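# Default minimal CMV core promoter. This is a placeholder carrying the
# commonly used ~60 bp minimal CMV fragment (TATA box + initiator); replace
# it via design_config(core_promoter_seq = ...) for construct synthesis.
MINCMV_PLACEHOLDER <- "TAGGCGTGTACGGTGGGAGGCCTATATAAGCAGAGCTCGTTTAGTGAACCGTCAGATCGC"

#' Promoter design configuration
#'
#' Design constants for tandem-array synthetic promoters: the total length
#' of binding sites to aim for (~120 bp; the repeat count is derived from
#' it), the spacer length between repeats (3 bp), the core promoter placed
#' downstream of the array, and the spacer screening stringency.
#'
#' @param target_site_bp Total binding-site length to approximate (default
#'   120).
#' @param spacer_len Spacer length in bp between repeats (default 3).
#' @param core_promoter_seq Core promoter sequence; the default is a
#'   placeholder minimal CMV fragment intended to be replaced for synthesis.
#' @param core_promoter_name Label for the core promoter feature.
#' @param screen_alpha Per-window tail probability used when screening
#'   spacers and validating designs (default 1e-4).
#' @param spacer_candidates Candidate spacer sequences tried in order;
#'   default all `4^spacer_len` strings in lexicographic (A<C<G<T) order.
#' @return List of class `DesignConfig`.
#' @export
design_config <- function(target_site_bp = 120L, spacer_len = 3L,
                          core_promoter_seq = MINCMV_PLACEHOLDER,
                          core_promoter_name = "minCMV",
                          screen_alpha = 1e-4,
                          spacer_candidates = NULL) {
  if (!is_count(target_site_bp) || target_site_bp < 4)
    stopf("design_config: target_site_bp must be an integer >= 4")
  if (!is_count(spacer_len) || spacer_len < 0)
    stopf("design_config: spacer_len must be a non-negative integer")
  if (!nzchar(core_promoter_seq))
    stopf("design_config: core_promoter_seq must be non-empty")
  if (is.null(spacer_candidates))
    spacer_candidates <- all_kmers(spacer_len)
  structure(list(target_site_bp = as.integer(target_site_bp),
                 spacer_len = as.integer(spacer_len),
                 core_promoter_seq = toupper(core_promoter_seq),
                 core_promoter_name = core_promoter_name,
                 screen_alpha = screen_alpha,
                 spacer_candidates = spacer_candidates),
            class = "DesignConfig")
}

all_kmers <- function(k) {
  if (k == 0) return("")
  grid <- do.call(expand.grid, c(rep(list(BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  sort(apply(grid, 1, paste, collapse = ""))
}

#' Number of tandem repeats for a target total site length
#'
#' `max(1, round(target_site_bp / site_len))` with half-up rounding, so the
#' repeated sites total the closest achievable multiple of the site length
#' to the target (~120 bp by default), ties rounding upward.
#'
#' @param site_len Binding-site length (>= 4).
#' @param target_site_bp Target total binding-site length (default 120).
#' @return Integer repeat count >= 1.
#' @export
repeat_count <- function(site_len, target_site_bp = 120L) {
  if (!is_count(site_len) || site_len < 4)
    stopf("repeat_count: site_len must be an integer >= 4")
  if (target_site_bp < site_len)
    stopf("repeat_count: target_site_bp (%d) < site_len (%d)",
          target_site_bp, site_len)
  max(1L, as.integer(floor(target_site_bp / site_len + 0.5)))
}

# Precompute scoring matrices + integer thresholds for a library once.
screening_library <- function(library, screen_alpha, background = rep(0.25, 4),
                              scale = 1000L) {
  lapply(library, function(p) {
    sm <- log_odds(p, background, scale = scale)
    thr <- suppressWarnings(threshold_for_pvalue(sm, screen_alpha))
    list(sm = sm, t_int = thr$int_threshold, threshold = thr$threshold)
  })
}

# Hit counts of every screened motif on a sequence (both strands).
count_library_hits <- function(seq, screened) {
  codes <- encode_seq(seq)
  vapply(screened, function(s) {
    n <- 0L
    for (st in 1:2) {
      m <- if (st == 1) s$sm$int_scores else rc_int_scores(s$sm$int_scores)
      n <- n + sum(window_scores(m, codes) >= s$t_int)
    }
    n
  }, 0L)
}

assemble_array <- function(site, spacers) {
  if (length(spacers) == 0) return(site)
  paste0(site, paste(vapply(spacers, function(sp) paste0(sp, site), ""),
                     collapse = ""))
}

# violation of an assembled array: deviation from the expected intended-hit
# count plus any off-target library hit
array_violation <- function(array_seq, screened, intended_id, expected_r) {
  hits <- count_library_hits(array_seq, screened)
  intended <- hits[[intended_id]]
  abs(intended - expected_r) + sum(hits[names(hits) != intended_id])
}

#' Choose screened spacers for a tandem array
#'
#' Deterministic first-fit search: each candidate spacer is first tried at
#' every junction simultaneously and accepted if the assembled array (sites
#' plus spacers, no core) contains exactly `r` hits of the intended motif
#' and no hit of any other library motif at the screening thresholds. If no
#' uniform candidate passes, junctions are filled left to right (first
#' candidate with a violation-free prefix array). If nothing passes, the
#' minimal-violation uniform candidate is used and a warning is attached.
#'
#' @param site_seq Strict consensus site to be repeated.
#' @param r Repeat count (>= 1).
#' @param screened Screening library from the internal precomputation in
#'   [build_promoter()]; a named list with one scoring matrix + threshold
#'   per motif.
#' @param intended_id Motif id whose hits are expected `r` times.
#' @param cfg A [design_config()].
#' @return Character vector of r - 1 spacers, with attribute `warning` set
#'   when only a violating assignment exists.
#' @export
choose_spacers <- function(site_seq, r, screened, intended_id, cfg) {
  if (!is_count(r) || r < 1) stopf("choose_spacers: r must be an integer >= 1")
  if (r == 1) return(character(0))
  for (cand in cfg$spacer_candidates) {
    spacers <- rep(cand, r - 1)
    if (array_violation(assemble_array(site_seq, spacers), screened,
                        intended_id, r) == 0)
      return(spacers)
  }
  # per-junction left-to-right first fit on growing prefixes
  spacers <- character(0)
  ok <- TRUE
  for (j in seq_len(r - 1)) {
    found <- FALSE
    for (cand in cfg$spacer_candidates) {
      prefix <- assemble_array(site_seq, c(spacers, cand))
      if (array_violation(prefix, screened, intended_id, j + 1) == 0) {
        spacers <- c(spacers, cand); found <- TRUE; break
      }
    }
    if (!found) { ok <- FALSE; break }
  }
  if (ok && length(spacers) == r - 1 &&
      array_violation(assemble_array(site_seq, spacers), screened,
                      intended_id, r) == 0)
    return(spacers)
  # fall back: minimal-violation uniform candidate
  viols <- vapply(cfg$spacer_candidates, function(cand)
    array_violation(assemble_array(site_seq, rep(cand, r - 1)), screened,
                    intended_id, r), 0)
  best <- cfg$spacer_candidates[which.min(viols)]
  out <- rep(best, r - 1)
  attr(out, "warning") <- sprintf(
    "no spacer assignment avoids spurious hits; using '%s' with violation score %d",
    best, min(viols))
  out
}

#' Build a tandem-array synthetic promoter for one motif
#'
#' Assembles, 5' to 3': r copies of the motif's strict consensus site
#' separated by screened spacers, followed by the core promoter. The repeat
#' count targets `cfg$target_site_bp` total site bp; spacers are screened
#' against the whole motif library; the finished construct is re-scanned to
#' populate the validation counts.
#'
#' @param pwm_obj The [pwm()] to design for.
#' @param library Motif library (named list of [pwm()]); `pwm_obj` is added
#'   if absent. Used for spacer screening and validation.
#' @param cfg A [design_config()].
#' @return Object of class `PromoterDesign`: `tf_name`, `motif_id`,
#'   `site_seq`, `repeats`, `spacer_seqs`, `full_seq`, `layout` (data.frame
#'   of 0-based half-open spans: type site/spacer/core, start, end),
#'   `core_promoter_name`, `validation` (list `intended_hits`,
#'   `unintended_hits`, `detail`), `warnings`.
#' @export
build_promoter <- function(pwm_obj, library, cfg = design_config()) {
  stopifnot(inherits(pwm_obj, "Pwm"), inherits(cfg, "DesignConfig"))
  if (!pwm_obj$id %in% vapply(library, `[[`, "", "id"))
    library <- c(library, list(pwm_obj))
  library <- unique_motif_ids(library)
  site <- consensus_site(pwm_obj, "strict")
  W <- nchar(site)
  if (cfg$target_site_bp < W)
    stopf("build_promoter: site width %d exceeds target_site_bp %d",
          W, cfg$target_site_bp)
  r <- repeat_count(W, cfg$target_site_bp)
  screened <- screening_library(library, cfg$screen_alpha)
  spacers <- choose_spacers(site, r, screened, pwm_obj$id, cfg)
  warn <- attr(spacers, "warning")
  array_seq <- assemble_array(site, as.character(spacers))
  full_seq <- paste0(array_seq, cfg$core_promoter_seq)

  # layout: r sites, r-1 spacers, 1 core => 2r spans (0-based half-open)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  pos <- 0L
  for (i in seq_len(r)) {
    starts <- c(starts, pos); ends <- c(ends, pos + W); types <- c(types, "site")
    pos <- pos + W
    if (i < r) {
      sl <- nchar(spacers[i])
      starts <- c(starts, pos); ends <- c(ends, pos + sl)
      types <- c(types, "spacer")
      pos <- pos + sl
    }
  }
  starts <- c(starts, pos); ends <- c(ends, pos + nchar(cfg$core_promoter_seq))
  types <- c(types, "core")

  design <- structure(
    list(tf_name = pwm_obj$tf_name, motif_id = pwm_obj$id, site_seq = site,
         repeats = r, spacer_seqs = as.character(spacers), full_seq = full_seq,
         layout = data.frame(type = types, start = starts, end = ends),
         core_promoter_name = cfg$core_promoter_name,
         validation = NULL, warnings = if (is.null(warn)) character(0) else warn),
    class = "PromoterDesign")
  design$validation <- validate_design(design, screened)
  design
}

#' @export
print.PromoterDesign <- function(x, ...) {
  cat(sprintf(
    "PromoterDesign %s: %d x %s (+%d bp spacers) + %s; %d bp total\n  intended hits %d, unintended %d%s\n",
    x$tf_name, x$repeats, x$site_seq,
    if (length(x$spacer_seqs)) nchar(x$spacer_seqs[1]) else 0,
    x$core_promoter_name, nchar(x$full_seq),
    x$validation$intended_hits, x$validation$unintended_hits,
    if (length(x$warnings)) paste0("\n  warning: ", x$warnings[1]) else ""))
  invisible(x)
}

#' Validate an assembled promoter design
#'
#' Scans both strands of the full construct (sites, spacers and core) with
#' every library motif. `intended_hits` counts hits of the design's own
#' motif that coincide with a designed site span; every other hit — other
#' motifs anywhere, or the design's motif outside its site spans — counts
#' as unintended.
#'
#' @param design A `PromoterDesign`.
#' @param screened Screening library (scoring matrices + thresholds); build
#'   one from PWMs with the same configuration used at design time, or pass
#'   the library used by [build_promoter()].
#' @return List: `intended_hits`, `unintended_hits`, `detail` (data.frame
#'   of per-motif hit counts).
#' @export
validate_design <- function(design, screened) {
  stopifnot(inherits(design, "PromoterDesign"))
  if (all(vapply(screened, inherits, TRUE, "Pwm")))
    screened <- screening_library(unique_motif_ids(screened), 1e-4)
  site_starts <- design$layout$start[design$layout$type == "site"]
  intended <- 0L; unintended <- 0L
  ids <- names(screened)
  per_motif <- integer(length(screened))
  codes <- encode_seq(design$full_seq)
  for (k in seq_along(screened)) {
    s <- screened[[k]]
    offs <- integer(0)
    for (st in 1:2) {
      m <- if (st == 1) s$sm$int_scores else rc_int_scores(s$sm$int_scores)
      offs <- c(offs, which(window_scores(m, codes) >= s$t_int) - 1L)
    }
    per_motif[k] <- length(offs)
    if (ids[k] == design$motif_id) {
      on_site <- sum(offs %in% site_starts)
      intended <- intended + on_site
      unintended <- unintended + (length(offs) - on_site)
    } else {
      unintended <- unintended + length(offs)
    }
  }
  list(intended_hits = intended, unintended_hits = unintended,
       detail = data.frame(motif_id = ids, hits = per_motif))
}

#' Write a design summary TSV
#'
#' @param designs List of `PromoterDesign` objects.
#' @param path Output path.
#' @export
write_designs_tsv <- function(designs, path) {
  rows <- lapply(designs, function(d) data.frame(
    tf_name = d$tf_name, motif_id = d$motif_id, site_seq = d$site_seq,
    repeats = d$repeats, total_site_bp = d$repeats * nchar(d$site_seq),
    spacer_len = if (length(d$spacer_seqs)) nchar(d$spacer_seqs[1]) else NA_integer_,
    full_length = nchar(d$full_seq),
    intended_hits = d$validation$intended_hits,
    unintended_hits = d$validation$unintended_hits,
    warnings = paste(d$warnings, collapse = "; ")))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
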