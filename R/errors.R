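# Classed conditions so callers (and tests) can distinguish failure modes.

bmi_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bmi_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_validation <- function(message) bmi_stop(message, "bmi_validation_error")
stop_parameter  <- function(message) bmi_stop(message, "bmi_parameter_error")
stop_format     <- function(message) bmi_stop(message, "bmi_format_error")
stop_range      <- function(message) bmi_stop(message, "bmi_range_error")
stop_shape      <- function(message) bmi_stop(message, "bmi_shape_error")
stop_estimation <- function(message) bmi_stop(message, "bmi_estimation_error")
stop_contract   <- function(message) bmi_stop(message, "bmi_contract_error")
stop_io         <- function(message) bmi_stop(message, "bmi_io_error")
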