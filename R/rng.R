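#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb each other.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a keyed substream seed
#'
#' Maps a global seed plus a string key (e.g. `"samples"`, or
#' `"08050001|cogd_only|rep37"`) to a seed in `[1, 2^31 - 2]` via a 32-bit
#' FNV-1a hash. The mapping depends only on (seed, key), never on processing
#' order, which gives per-stratum / per-rep RNG substreams that are
#' independent of loop order.
#'
#' @param seed integer global seed.
#' @param key character scalar naming the substream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  bytes <- utf8ToInt(paste0(key, "#", as.integer(seed)))
  # FNV-1a in double arithmetic; all intermediates stay < 2^53 exactly
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves (stays exact in doubles)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483646) + 1L
}
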