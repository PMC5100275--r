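# Deterministic substream handling. One master seed spawns an independent
# 31-bit seed per (stream index), so per-locus / per-replicate streams do not
# shift when the number of loci or replicates changes.

# Lehmer-style double-precision mixer; 48271 * 2^31 < 2^53 so the modular
# arithmetic is exact in doubles.
mix_seed <- function(master, index) {
  m <- 2147483647
  x <- (abs(as.double(master)) + 1) %% m
  x <- (x * 48271 + as.double(index) %% m) %% m
  x <- (x * 48271 + 12345) %% m
  x <- (x * 48271 + 67867967) %% m
  as.integer(x)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stream-index offsets reserved for non-locus randomness within one
# experiment (loci use indices 1..n_loci).
.STREAM_MOTIFS <- 1000000007
.STREAM_PAIRING <- 1000000011
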