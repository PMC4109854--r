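#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded internals never perturb a caller's
#' random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' MD5 hash of a character vector
#'
#' Stable content hash used to fingerprint gene universes and input files
#' in ranking-database metadata and run manifests.
#'
#' @param x character vector.
#' @return lowercase hex md5 string.
#' @keywords internal
hash_strings <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}

# Derive a stream-specific 32-bit sub-seed from a master seed, so that
# independent stages seeded from one master seed draw independent streams.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
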