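#' @keywords internal
"_PACKAGE"

# Deterministic child seeds: one master seed, one stream per cohort/stage.
# Kept strictly below 2^31 so set.seed() accepts them on every platform.
child_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Evaluate `code` under a local RNG stream; restores the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "chr1" / "Chr1" / "1" -> "1"
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))
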