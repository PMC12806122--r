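#' Ungapped similarity between two PWMs
#'
#' Slides `b` over `a` at every ungapped offset with at least 4 overlapping
#' columns, in both orientations of `b`, and returns the alignment
#' maximizing the mean column-wise Pearson correlation between probability
#' columns. Ties are broken by smaller |offset|, then by `same` orientation
#' over `reverse_complement`.
#'
#' @param a,b [pwm()] objects of width >= 4.
#' @return List of class `MotifMatch`: `motif_a`, `motif_b`, `offset`
#'   (position of b's first column relative to a's, 0-based), `orientation`
#'   (`"same"` or `"reverse_complement"`), `similarity` in \[-1, 1\].
#' @export
motif_similarity <- function(a, b) {
  stopifnot(inherits(a, "Pwm"), inherits(b, "Pwm"))
  if (a$width < 4 || b$width < 4)
    stopf("motif_similarity: both motifs must have width >= 4")
  best <- list(similarity = -Inf, offset = 0L, orientation = "same")
  for (orient in c("same", "reverse_complement")) {
    bm <- if (orient == "same") b$prob else {
      m <- b$prob[c(4, 3, 2, 1), rev(seq_len(b$width)), drop = FALSE]
      rownames(m) <- BASES
      m
    }
    for (d in (-(b$width - 4L)):(a$width - 4L)) {
      js <- max(1L, 1L - d):min(b$width, a$width - d)
      if (length(js) < 4) next
      cors <- vapply(js, function(j) column_cor(a$prob[, j + d], bm[, j]), 0)
      sim <- mean(cors)
      better <- sim > best$similarity + 1e-12 ||
        (abs(sim - best$similarity) <= 1e-12 &&
           (abs(d) < abs(best$offset) ||
              (abs(d) == abs(best$offset) && orient == "same" &&
                 best$orientation == "reverse_complement")))
      if (better)
        best <- list(similarity = sim, offset = as.integer(d), orientation = orient)
    }
  }
  structure(list(motif_a = a$id, motif_b = b$id, offset = best$offset,
                 orientation = best$orientation, similarity = best$similarity),
            class = "MotifMatch")
}

# Pearson correlation of two probability columns; a flat (zero-variance)
# column carries no shape information, so its correlation is defined as 0.
column_cor <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(0)
  stats::cor(x, y)
}

#' Intersect enriched motifs across datasets
#'
#' Returns the motifs significantly enriched (p < `p_max`) in every one of K
#' independently analyzed datasets — the cross-dataset (or cross-species)
#' conserved motif set. `by_id` matches motif ids case-insensitively;
#' `by_similarity` greedily matches each dataset-1 enriched motif to the
#' most similar unused enriched motif of every other dataset, requiring PWM
#' similarity >= `sim_min` (see [motif_similarity()]).
#'
#' @param result_sets List of K [motif_enrichment()] results.
#' @param libraries List of K motif libraries (named lists of [pwm()]);
#'   required for `by_similarity`.
#' @param p_max Per-dataset significance threshold (default 0.05).
#' @param match_mode `"by_id"` (default) or `"by_similarity"`.
#' @param sim_min Minimum PWM similarity for a cross-library match
#'   (default 0.80).
#' @return data.frame of class `ConservedMotifSet` with `canonical_id`
#'   (dataset-1 motif id) and per-dataset `id_k`, `p_k`, `q_k` columns,
#'   sorted by the maximum per-dataset p ascending; attribute `k` holds the
#'   dataset count.
#' @export
intersect_enriched <- function(result_sets, libraries = NULL, p_max = 0.05,
                               match_mode = c("by_id", "by_similarity"),
                               sim_min = 0.80) {
  match_mode <- match.arg(match_mode)
  K <- length(result_sets)
  if (K < 2) stopf("intersect_enriched: need >= 2 result sets (got %d)", K)
  if (sim_min <= 0 || sim_min > 1)
    stopf("intersect_enriched: sim_min must be in (0, 1]")
  enriched <- lapply(result_sets, function(r) r[r$p_value < p_max, , drop = FALSE])

  if (match_mode == "by_id") {
    matched_ids <- lapply(seq_len(K), function(k) {
      # map dataset-1 id -> dataset-k id via case-insensitive equality
      ids1 <- enriched[[1]]$motif_id
      idsk <- enriched[[k]]$motif_id
      idsk[match(tolower(ids1), tolower(idsk))]
    })
  } else {
    if (is.null(libraries) || length(libraries) != K)
      stopf("intersect_enriched: by_similarity needs one library per dataset")
    ids1 <- enriched[[1]]$motif_id
    matched_ids <- vector("list", K)
    matched_ids[[1]] <- ids1
    for (k in 2:K) {
      idsk <- enriched[[k]]$motif_id
      assigned <- rep(NA_character_, length(ids1))
      if (length(ids1) && length(idsk)) {
        sim <- matrix(-Inf, length(ids1), length(idsk))
        for (i in seq_along(ids1)) for (j in seq_along(idsk))
          sim[i, j] <- motif_similarity(libraries[[1]][[ids1[i]]],
                                        libraries[[k]][[idsk[j]]])$similarity
        # greedy best-first one-to-one matching
        repeat {
          m <- which(sim == max(sim), arr.ind = TRUE)
          if (max(sim) < sim_min) break
          i <- m[1, 1]; j <- m[1, 2]
          assigned[i] <- idsk[j]
          sim[i, ] <- -Inf; sim[, j] <- -Inf
        }
      }
      matched_ids[[k]] <- assigned
    }
  }

  keep <- Reduce(`&`, lapply(matched_ids, function(x) !is.na(x)))
  ids1 <- enriched[[1]]$motif_id
  out <- data.frame(canonical_id = ids1[keep])
  for (k in seq_len(K)) {
    ids_k <- matched_ids[[k]][keep]
    ri <- match(ids_k, enriched[[k]]$motif_id)
    out[[sprintf("id_%d", k)]] <- ids_k
    out[[sprintf("p_%d", k)]] <- enriched[[k]]$p_value[ri]
    out[[sprintf("q_%d", k)]] <- enriched[[k]]$q_value[ri]
  }
  if (nrow(out)) {
    pmaxes <- do.call(pmax, out[sprintf("p_%d", seq_len(K))])
    out <- out[order(pmaxes, out$canonical_id), ]
    rownames(out) <- NULL
  }
  attr(out, "k") <- K
  class(out) <- c("ConservedMotifSet", "data.frame")
  out
}

#' Write a conserved-motif report TSV
#'
#' @param conserved [intersect_enriched()] result.
#' @param path Output path.
#' @export
write_conserved_tsv <- function(conserved, path) {
  utils::write.table(as.data.frame(conserved), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
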