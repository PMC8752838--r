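# Structured error conditions. Every user-facing failure is a classed condition
# so callers (and tests) can discriminate input-format, validation, configuration,
# data-gap and domain errors without string matching.

paf_stop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "paf_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

paf_input_error <- function(message, ...) {
  paf_stop("paf_input_error", message, call = sys.call(-1), ...)
}

paf_validation_error <- function(message, ...) {
  paf_stop("paf_validation_error", message, call = sys.call(-1), ...)
}

paf_config_error <- function(message, ...) {
  paf_stop("paf_config_error", message, call = sys.call(-1), ...)
}

paf_data_gap_error <- function(message, ...) {
  paf_stop("paf_data_gap_error", message, call = sys.call(-1), ...)
}

paf_domain_error <- function(message, ...) {
  paf_stop("paf_domain_error", message, call = sys.call(-1), ...)
}

paf_lookup_error <- function(message, ...) {
  paf_stop("paf_lookup_error", message, call = sys.call(-1), ...)
}
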