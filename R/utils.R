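#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic substream seeds: a single user seed expands into independent
# streams (placement, oxd, mosaic, noise, ...) so that toggling one source of
# randomness leaves the draws of the others unchanged.
substream_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 100003L
  s <- (as.numeric(seed) * 10007 + h * 1009 + as.numeric(index) * 97) %% 2147483629
  as.integer(s) + 1L
}

with_stream <- function(seed, stream, index = 0L, code) {
  withr::with_seed(substream_seed(seed, stream, index), code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# Truncated-normal draws by inverse-CDF so a fixed seed maps to fixed values
# independent of rejection paths.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
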