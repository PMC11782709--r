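# compact configurations used across tests: coarse isochromat grids and short
# cycles keep individual simulations in the tens of milliseconds
quick_config <- function(...) {
  defaults <- list(n_tr_per_cycle = 30, n_trigger_tr = 4, n_cycles = 4,
                   n_slice = 7, n_spoiler = 24)
  args <- utils::modifyList(defaults, list(...))
  do.call(sequence_config, args)
}

# full-resolution study configuration (150 TR cycles, converged isochromats)
study_config <- function(...) {
  do.call(sequence_config, list(...))
}

deviation_for <- function(config, tissue, bg, n_avg = 20) {
  series <- phase_contrast(run_sequence(config, tissue, bg = bg))
  steady_state_deviation(series, bg, n_avg = n_avg)
}
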