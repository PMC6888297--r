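# shared fixtures: shipped defaults and a cached physiological state
defaults <- default_parameters()
phys <- physiological_state(defaults)

random_valid_state <- function(params) {
  tot <- totals(params)
  stats::setNames(stats::runif(4) * tot, c("A", "M", "U", "G"))
}
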