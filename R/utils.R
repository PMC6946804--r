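# internal argument checking helpers

stop_input <- function(...) {
  stop(structure(
    class = c("bathypan_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("bathypan_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_config("'", name, "' must be a single number in [", min, ", ", max, "]")
  as.numeric(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input("'", name, "' is missing required column(s): ",
               paste(missing, collapse = ", "))
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
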