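#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the framework draws its own seed from the
#' experiment's global seed and a stage name, so that adding or reordering
#' stages never perturbs the random stream of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  # 7919 is an arbitrary fixed prime; doubles hold the product exactly
  as.integer((h + abs(as.numeric(seed)) * 7919) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validation error that names the offending field.
abort_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_range_pair <- function(x, field, lower_min = 1) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)))
    abort_field(field, "must be a numeric range of length 2")
  if (x[1] > x[2]) abort_field(field, "lower bound exceeds upper bound")
  if (x[1] < lower_min)
    abort_field(field, sprintf("lower bound must be >= %d", lower_min))
  invisible(x)
}

# Uniform integer draw in [lo, hi] using the current RNG stream.
runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
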