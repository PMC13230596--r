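# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Condition constructors ------------------------------------------------

llps_error <- function(class, message, ..., call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "llps_error", "error", "condition"),
    list(message = message, call = call., ...)
  ))
}

llps_validation_error <- function(message, ...) {
  llps_error("llps_validation_error", message, ..., call. = sys.call(-1))
}

llps_config_error <- function(message, ...) {
  llps_error("llps_config_error", message, ..., call. = sys.call(-1))
}

llps_normalization_error <- function(message, raw = NULL) {
  llps_error("llps_normalization_error", message, raw = raw,
             call. = sys.call(-1))
}

llps_transport_error <- function(message) {
  llps_error("llps_transport_error", message, call. = sys.call(-1))
}

## Text folding ----------------------------------------------------------

# casefold + collapse internal whitespace + trim
fold_text <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# unit symbols: micro sign (U+00B5) and Greek mu (U+03BC) both fold to "u"
fold_unit <- function(x) {
  x <- gsub("µ|μ", "u", x)
  tolower(gsub("\\s+", "", x))
}

## Number formatting -----------------------------------------------------

# Shortest decimal representation that reparses to the identical double.
# Keeps CSV/JSON round trips the identity and repeated writes byte-stable.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == trunc(v) && abs(v) < 1e15) {
      s <- sprintf("%.0f", v)
      if (as.numeric(s) == v) return(s)
    }
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
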