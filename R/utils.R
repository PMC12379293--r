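## Internal helpers shared across modules.

# slot sizes of the recorder: 0.5 ms detection time, 0.25 us arrival-time
# difference. Both are exactly representable in binary floating point, so
# multiples can be checked exactly after a round().
.TIME_STEP_MS <- 0.5
.TD_STEP_US <- 0.25

.is_multiple <- function(x, step) {
  abs(x / step - round(x / step)) < 1e-9
}

.quantize <- function(x, step) {
  round(x / step) * step
}

#' Coefficient of variation (sample SD / mean)
#' @noRd
.cv <- function(x) stats::sd(x) / mean(x)

#' Half-up rounding of a proportion to integer percent
#'
#' Converts a proportion in \[0, 1\] to an integer percentage using
#' round-half-up (so 0.945 -> 95, 0.425 -> 43), the convention used for all
#' reported detection rates and classification metrics. Base R `round()`
#' rounds half to even and is not used for reporting.
#'
#' @param p numeric vector of proportions in \[0, 1\] (NA passed through).
#' @return integer percentage vector.
#' @examples
#' percentHalfUp(c(0.94989, 0.26087))
#' @export
percentHalfUp <- function(p) {
  ifelse(is.na(p), NA_integer_, as.integer(floor(p * 100 + 0.5)))
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Classed error constructors so the CLI can map conditions to exit codes:
## schema/config problems -> ptSchemaError, data-content problems ->
## ptValidationError.
.schema_error <- function(msg) {
  stop(structure(class = c("ptSchemaError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.validation_error <- function(msg) {
  stop(structure(class = c("ptValidationError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
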