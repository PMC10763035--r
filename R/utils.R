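`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' @keywords internal
undefined_metric <- function(metric, msg) {
  stop(errorCondition(sprintf("undefined metric '%s': %s", metric, msg),
                      class = c("promval_undefined_metric", "error", "condition")))
}

## Lower median: for even n the smaller of the two central order statistics.
## Chosen so the intercept-only LAD shortcut coincides with a vertex of the
## equivalent linear program (a data point), see lad_fit().
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

## Truncated normal / log-normal samplers via inverse-CDF (deterministic under
## the current RNG stream, no rejection loops).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

rlnorm_trunc <- function(n, meanlog, sdlog, upper = Inf) {
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, phi), meanlog, sdlog)
}

## Format doubles so they round-trip exactly through text (17 significant
## digits is sufficient for IEEE doubles).
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}
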