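#' @keywords internal
"_PACKAGE"

## NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

## Validation error naming the offending field
stop_field <- function(field, msg) {
  stop(structure(
    class = c("wbrt_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg),
         call = sys.call(-1), field = field)
  ))
}

check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_field(field, msg)
  invisible(TRUE)
}

## Run `expr` under a temporary RNG state seeded with `seed`; restores the
## caller's RNG stream so phantom generation never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Structured failure used by the DRR segmenter when required structures
## cannot be located; callers (the pipeline) catch this class to trigger the
## QA "flag" path instead of crashing.
segmentation_failure <- function(missing, message = NULL) {
  structure(
    class = c("wbrt_segmentation_failure", "error", "condition"),
    list(message = message %||%
           sprintf("DRR segmentation failed; structure(s) not found: %s",
                   paste(missing, collapse = ", ")),
         call = NULL, missing = missing)
  )
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
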