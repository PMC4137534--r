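#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call, so library functions never perturb a
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

#' 32-bit FNV-1a hash of a string
#'
#' Used to derive stable per-cell seeds from grid-cell keys so that adding or
#' removing grid entries never changes another cell's random stream.
#' Implemented with 16-bit limb arithmetic so all intermediates stay exact in
#' double precision.
#'
#' @param s a single character string.
#' @return a double holding an integer in `[0, 2^32)`.
#' @keywords internal
fnv1a32 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 2166136261
  prime_lo <- 403   # 16777619 = 256 * 65536 + 403
  prime_hi <- 256
  for (b in utf8ToInt(s)) {
    h <- bitwXor32(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    # (hi*2^16 + lo) * (prime_hi*2^16 + prime_lo) mod 2^32
    h <- ((hi * prime_lo + lo * prime_hi) %% 65536) * 65536 + lo * prime_lo
    h <- h %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # xor for doubles holding 32-bit unsigned values
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

#' Derive a per-cell seed from a master seed and a string key
#'
#' @param master_seed integer master seed.
#' @param key character key identifying the cell.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master_seed, key) {
  h <- fnv1a32(key)
  as.integer((as.double(master_seed) + h) %% 2147483646) + 1L
}
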