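# Internal helpers: seeded substreams and small shared utilities.

# Derive a reproducible 32-bit sub-seed from a master seed and a stream label,
# so that adding a new generator never perturbs the draws of existing ones.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (i in seq_along(codes)) {
    h <- (h * 31 + codes[i]) %% 2147483647
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Evaluate expr with the RNG seeded from (seed, label), restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

# Uppercase DNA validation
check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (!nzchar(x) || grepl("[^ACGT]", x)) {
    stop(what, " must be a non-empty string over {A,C,G,T}: ", x, call. = FALSE)
  }
  x
}

# Serialize a length-only allele as a perfect repeat of `unit` truncated or
# recycled to `len` bases (used only when a VCF sequence column is required).
unit_fill <- function(unit, len) {
  if (len == 0L) return("")
  reps <- ceiling(len / nchar(unit))
  substr(strrep(unit, reps), 1L, len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
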