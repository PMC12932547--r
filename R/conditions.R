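# Typed condition helpers. Every user-facing validation failure carries the
# class "irmdma_error" plus a specific subclass so callers (and the CLI) can
# dispatch on the failure kind instead of parsing messages.

stop_irmdma <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "irmdma_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_validation <- function(msg) stop_irmdma(msg, "irmdma_validation_error")
stop_degenerate <- function(msg) stop_irmdma(msg, "irmdma_degenerate_error")
stop_config <- function(msg) stop_irmdma(msg, "irmdma_config_error")

warn_irmdma <- function(msg, class = "irmdma_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
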