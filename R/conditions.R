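## Typed error conditions. The CLI maps these to exit codes
## (input 2, degenerate reference 3, parameter/config 4).

stopInput <- function(...) {
  stop(errorCondition(paste0(...), class = c("nailsenseInputError",
                                             "nailsenseError")))
}

stopParameter <- function(...) {
  stop(errorCondition(paste0(...), class = c("nailsenseParameterError",
                                             "nailsenseError")))
}

stopDegenerateReference <- function(...) {
  stop(errorCondition(paste0(...), class = c("nailsenseDegenerateReferenceError",
                                             "nailsenseError")))
}

stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("nailsenseConfigError",
                                             "nailsenseError")))
}
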