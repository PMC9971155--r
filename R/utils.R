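# Internal helpers shared across modules.

inv_logit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run-log: a character vector of machine-parsable "LEVEL|stage|message" lines
# accumulated on objects via the "run_log" attribute.
log_line <- function(level, stage, msg) {
  sprintf("%s|%s|%s", level, stage, msg)
}

append_log <- function(x, lines) {
  attr(x, "run_log") <- c(attr(x, "run_log"), lines)
  x
}

#' Retrieve the run log attached to a dyadnet object
#'
#' Readers, the generator and the pipeline attach a plain-text run log
#' (one `LEVEL|stage|message` line per event) recording exclusions,
#' warnings and seeds.
#'
#' @param x an object returned by a dyadnet function.
#' @return character vector of log lines (possibly empty).
#' @export
run_log <- function(x) attr(x, "run_log") %||% character()

# Split semicolon-joined id fields into character vectors; "" -> character(0).
split_ids <- function(x, sep = ";") {
  out <- strsplit(x, sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_ids <- function(lst, sep = ";") {
  vapply(lst, paste, character(1), collapse = sep)
}

stop_dyadnet <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

warn_dyadnet <- function(stage, fmt, ...) {
  warning(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
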