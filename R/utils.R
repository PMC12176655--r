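# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    abort_config("'%s' must be finite and > 0", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    abort_config("'%s' must be finite and >= 0", name)
  invisible(x)
}

# lognormal with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

hours_to_frames <- function(h, frame_interval) h * 60 / frame_interval

frames_to_hours <- function(f, frame_interval) f * frame_interval / 60

# deterministic substream seed derived from a base seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
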