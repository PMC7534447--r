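# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from (seed, tag) so independent
# generator streams inside one simulator do not collide.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse-complement preserving character case; IUPAC ambiguity codes
# are complemented, other characters (e.g. N) map to themselves.
reverse_complement <- function(x) {
  from <- "ACGTRYSWKMBDHVacgtryswkmbdhv"
  to   <- "TGCAYRSWMKVHDBtgcayrswmkvhdb"
  comp <- chartr(from, to, x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
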