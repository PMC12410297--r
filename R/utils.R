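# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Normal draw truncated below at `lower` (rejection sampling; exact mean/SD
# only in the untruncated limit, which is the regime used by the cohorts).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (any(mean <= lower)) stop("degenerate truncated draw: mean <= lower with sd = 0")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x > lower) break
    }
    out[i] <- x
  }
  out
}

# Round half away from zero to integer (base round() is half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Resolve a 3D/4D volume argument: NIfTI file path or in-memory array.
as_volume <- function(x, what = "volume") {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.array(RNifti::readNifti(x))
  }
  if (!is.array(x)) stop(sprintf("'%s' must be an array or a NIfTI file path", what))
  x
}

# 31-bit polynomial hash of a config (arbitrary R objects) for provenance stamps.
config_hash <- function(x) {
  s <- as.character(jsonlite::serializeJSON(x, digits = 15))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
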