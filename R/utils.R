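# internal validation helpers

stop_config <- function(...) {
  stop(structure(
    class = c("rarecascade_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_config(what, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
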