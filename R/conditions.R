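# Classed conditions so callers can distinguish failure modes.

stop_gait <- function(type, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("gait_", type), "gait_error")))
}

# type tags used across the package:
#   format        - unreadable/malformed file
#   parameter     - invalid argument value
#   empty_input   - no usable points/frames
#   degenerate    - feature undefined (zero-norm projection, ambiguous normal)
#   insufficient  - too few samples to fit/evaluate
#   evaluation    - benchmark structure invalid
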