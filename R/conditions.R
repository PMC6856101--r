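# Structured error conditions. Every user-facing failure carries the class
# "lmi_error" plus a specific subclass so callers (and the CLI) can map
# failures to exit codes: config errors vs data errors.

lmi_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "lmi_error", "error"), ...))
}

lmi_config_error <- function(msg, class = character()) {
  lmi_error(msg, c(class, "lmi_config_error"))
}

lmi_data_error <- function(msg, class = character()) {
  lmi_error(msg, c(class, "lmi_data_error"))
}
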