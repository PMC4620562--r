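# Small systems and short protocols shared across tests.

# single effective state: both diabats identical, so the ground surface is a
# plain harmonic well shifted by -h12
harmonic_system <- function(k = 40, x0 = 0, h12 = 0, n_bath = 0L) {
  evb_system(diabatic_surface(k, x0, 0), diabatic_surface(k, x0, 0),
             h12 = h12, n_bath = n_bath,
             domain = c(x0 - 1.5, x0 + 1.5))
}

# two displaced equal-stiffness wells, offset alpha: the two-state workhorse
two_well_system <- function(k = 60, d = 2, alpha = -5, h12 = 1,
                            n_bath = 0L, bath = NULL) {
  args <- list(state1 = diabatic_surface(k, 0, 0),
               state2 = diabatic_surface(k, d, alpha),
               h12 = h12, n_bath = n_bath)
  if (!is.null(bath)) args$bath <- bath
  do.call(evb_system, args)
}

# protocol short enough for unit tests, long enough to be in equilibrium;
# any sampling_protocol() argument can be overridden
short_protocol <- function(...) {
  args <- utils::modifyList(list(steps_sample_per_window = 8000L,
                                 steps_equil_per_window = 1000L,
                                 steps_per_heating_stage = 500L,
                                 steps_final_equil = 2000L),
                            list(...))
  do.call(sampling_protocol, args)
}

# thin autocorrelated samples to roughly independent ones for KS testing
thin <- function(x, by = 25L) x[seq(1L, length(x), by = by)]
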