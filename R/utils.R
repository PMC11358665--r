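POSITIVE <- "positive"
NEGATIVE <- "negative"

#' Round half away from zero
#'
#' Display rounding used throughout reports: percentages to one decimal,
#' counts to the nearest integer, with exact halves rounded away from zero
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Coerce assorted binary-label encodings to "positive"/"negative"
#'
#' Accepts logical (`TRUE` = positive), numeric 0/1, or the strings
#' `"positive"`/`"negative"` (case-insensitive). `NA` passes through.
#'
#' @param x vector of labels.
#' @param what label name used in error messages.
#' @return character vector of `"positive"`/`"negative"`.
#' @export
as_binary_label <- function(x, what = "label") {
  if (is.logical(x)) return(ifelse(x, POSITIVE, NEGATIVE))
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) {
      stop(sprintf("numeric %s must be 0/1; offending values: %s",
                   what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
    return(ifelse(x == 1, POSITIVE, NEGATIVE))
  }
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    bad <- !is.na(lx) & !lx %in% c(POSITIVE, NEGATIVE)
    if (any(bad)) {
      stop(sprintf("%s values must be 'positive' or 'negative'; offending values: %s",
                   what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
    return(lx)
  }
  stop(sprintf("cannot interpret %s of class %s as a binary label",
               what, paste(class(x), collapse = "/")), call. = FALSE)
}

# Run `code` with a fixed seed, then restore the caller's RNG state, so that
# seeded operations are reproducible without perturbing the global stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

stopifnot_probability <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single number in [0, 1], got %s",
                 what, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
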