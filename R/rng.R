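# Counter-based per-person random-number substreams.
#
# The simulation engine never consumes R's global RNG stream: every uniform it
# needs is a pure function of (root seed, person id, step index, channel).
# This makes cohort results invariant to the order in which persons are
# processed and lets a single person be re-simulated bit-identically.
#
# Construction: the counter words are absorbed one by one into a 32-bit state
# through a murmur3-style finalizer (xor-shift / multiply), giving nonlinear
# mixing — an affine (LCG-only) mixer would leave exact lattice relationships
# between channels of the same counter, correlating e.g. event-clock and
# case-fatality draws. All arithmetic is exact in doubles: 32-bit values are
# manipulated via 16-bit halves so no product exceeds 2^53.

.P32 <- 4294967296 # 2^32

# xor of two 32-bit values carried as doubles
.xor32 <- function(x, y) {
  bitwXor(x %/% 65536, y %/% 65536) * 65536 + bitwXor(x %% 65536, y %% 65536)
}

# (a * b) mod 2^32 for 32-bit doubles, exact
.mul32 <- function(a, b) {
  (((a %/% 65536) * b) %% 65536 * 65536 + (a %% 65536) * b) %% .P32
}

# murmur3 32-bit finalizer
.fmix32 <- function(h) {
  h <- .xor32(h, h %/% 65536)        # h ^= h >> 16
  h <- .mul32(h, 2246822507)         # 0x85ebca6b
  h <- .xor32(h, h %/% 8192)         # h ^= h >> 13
  h <- .mul32(h, 3266489909)         # 0xc2b2ae35
  .xor32(h, h %/% 65536)             # h ^= h >> 16
}

#' Counter-based uniform variates for per-person substreams
#'
#' Deterministic uniforms indexed by `(seed, id, step, channel)`. Used by the
#' discrete-event engine so that each simulated person owns an independent
#' random substream: results do not depend on cohort ordering or on how the
#' cohort is chunked, and draws on different channels of the same step are
#' mutually unstructured.
#'
#' @param seed Integer root seed (non-negative).
#' @param id Integer vector of person identifiers (non-negative).
#' @param step Integer simulation step counter (scalar or vector like `id`).
#' @param channel Integer channel within the step (scalar); distinct draws
#'   within one step use distinct channels.
#' @return Numeric vector of uniforms strictly inside (0, 1), one per `id`.
#' @examples
#' substream_uniform(1L, 1:5, step = 3, channel = 1)
#' @export
substream_uniform <- function(seed, id, step, channel) {
  stopifnot(length(seed) == 1L, seed >= 0, all(id >= 0), all(step >= 0),
            length(channel) == 1L, channel >= 0)
  h <- .fmix32(seed %% .P32)
  h <- .fmix32(.xor32(h, id %% .P32))
  h <- .fmix32(.xor32(h, step %% .P32))
  h <- .fmix32(.xor32(h, channel %% .P32))
  (h + 0.5) / .P32
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the previous
# global RNG state afterwards (so callers' streams are untouched).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
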