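#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals (display convention used by
# the source tables; base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split ";"-joined code strings into a list of character vectors.
split_codes <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(codes) {
  vapply(codes, paste, character(1), collapse = ";")
}

# Condition helpers: input errors (bad data) vs configuration errors (bad
# arguments / config files). The CLI maps these to distinct exit codes.
abort_input <- function(msg) {
  stop(structure(
    class = c("phenoval_input_error", "phenoval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(msg) {
  stop(structure(
    class = c("phenoval_config_error", "phenoval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort_config(sprintf("`%s` must be a single number in [%s, %s]",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}
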