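#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# integer encoding: A=1 C=2 G=3 T=4, anything else (incl. N)=5
encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], BASES)
  codes[is.na(codes)] <- 5L
  codes
}

decode_seq <- function(codes) {
  paste(c(BASES, "N")[codes], collapse = "")
}

revcomp_seq <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# stream so simulation helpers do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)

check_freqs <- function(freqs, what = "background") {
  if (length(freqs) != 4 || any(!is.finite(freqs)) || any(freqs < 0))
    stopf("%s must be 4 non-negative finite frequencies", what)
  if (abs(sum(freqs) - 1) > 1e-6)
    stopf("%s frequencies must sum to 1 (got %.8f)", what, sum(freqs))
  freqs
}
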