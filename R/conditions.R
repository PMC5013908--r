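# Classed conditions so callers (and the CLI) can distinguish failure modes:
# configuration errors (bad options), input errors (bad data), domain errors
# (argument outside its mathematical domain), numerical errors (non-convergence).

abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("wincurse_config_error", "wincurse_error"),
                      call = call))
}

abort_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("wincurse_input_error", "wincurse_error"),
                      call = call))
}

abort_domain <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("wincurse_domain_error", "wincurse_error"),
                      call = call))
}

abort_numerical <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("wincurse_numerical_error", "wincurse_error"),
                      call = call))
}
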