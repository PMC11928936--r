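#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-seed from a base seed
#'
#' Counter-based sub-seeding keeps per-scene and per-arm random streams
#' reproducible independently of iteration order. The result always fits in a
#' 32-bit signed integer.
#'
#' @param seed Base integer seed.
#' @param k Counter (non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  as.integer((abs(seed) * 48271 + k * 9973 + 1) %% 2147483647L)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

# Deterministic 64-bit-ish checksum of an R object (for report provenance).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x, control = "all"), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((h * 16777619) %% 2^31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
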