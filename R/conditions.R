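#' @keywords internal
#' @noRd
abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("apobecedit_", class), "apobecedit_error",
              "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_param <- function(msg) abort(msg, "parameter_error")
stop_input <- function(msg) abort(msg, "input_error")
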