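#' @keywords internal
"_PACKAGE"

## Validation failures carry the "limbvolValidationError" condition class so
## that callers (and the command-line wrapper) can distinguish bad input
## (exit code 2) from internal faults (exit code 1).
vstop <- function(fmt, ..., field = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("limbvolValidationError", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  )
  stop(cond)
}

assertScalarNumber <- function(x, name, positive = FALSE, nonNegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    vstop("'%s' must be a single finite number", name, field = name)
  if (positive && x <= 0)
    vstop("'%s' must be > 0 (got %g)", name, x, field = name)
  if (nonNegative && x < 0)
    vstop("'%s' must be >= 0 (got %g)", name, x, field = name)
  invisible(x)
}

## Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's generator state afterwards. seed = NULL leaves the global stream
## untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

normalizeSex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || is.na(sex))
    vstop("'sex' must be \"male\" or \"female\"", field = "sex")
  s <- switch(tolower(sex),
    "m" = , "male" = "male",
    "f" = , "female" = "female",
    vstop("unknown sex code '%s' (use \"male\" or \"female\")", sex,
          field = "sex"))
  s
}

normalizeLimbType <- function(limbType) {
  if (!is.character(limbType) || length(limbType) != 1L || is.na(limbType))
    vstop("'limbType' must be \"arm\" or \"leg\"", field = "limbType")
  switch(tolower(limbType),
    "arm" = "arm",
    "leg" = "leg",
    vstop("unknown limb type '%s' (use \"arm\" or \"leg\")", limbType,
          field = "limbType"))
}
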