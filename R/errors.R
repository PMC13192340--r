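# Structured condition helpers. Every user-facing failure goes through
# pm_stop() with a condition class so callers (and the CLI) can distinguish
# input/validation problems from internal ones.

pm_stop <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message,
                      ...,
                      class = c(class, "popmortgen_error"),
                      call = call))
}

pm_parse_error <- function(message, row = NA, column = NA_character_) {
  pm_stop("popmortgen_parse_error",
          message, row = row, column = column, call = sys.call(-2))
}

pm_validation_error <- function(message, ...) {
  pm_stop("popmortgen_validation_error", message, ..., call = sys.call(-2))
}

pm_domain_error <- function(message, ...) {
  pm_stop("popmortgen_domain_error", message, ..., call = sys.call(-2))
}
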