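#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Emit a package notice
#'
#' Thin wrapper over [message()] so that informational notices (clamped
#' predictors, ignored columns, empty subgroups) share one prefix and can be
#' silenced with `suppressMessages()`.
#' @noRd
notify <- function(...) message("cvdscreen: ", ...)

stop_input <- function(...) stop(..., call. = FALSE)

## Deterministic child seeds: expand one root seed into per-module streams
## without exceeding .Machine$integer.max.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 16807L) %% 2147483562L
}
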