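# shared simulation presets for tests

# small, fast glottis parameter sets
sim_params <- function(...) {
  args <- utils::modifyList(
    list(duration_s = 0.4, frame_height = 60, frame_width = 160),
    list(...))
  do.call(glottis_sim_params, args)
}

# a "soft" phonation configuration: low amplitude, near-sinusoidal cycle,
# quick growth
soft_params <- function(...) {
  sim_params(steady_amplitude_px = 8, closed_quotient = 0.05,
             growth_tau_cycles = 1.5, prephonation_delay_ms = 50, ...)
}

# a "loud" configuration: high amplitude, long closed phase, slower growth,
# longer pre-phonation delay
loud_params <- function(...) {
  sim_params(steady_amplitude_px = 25, closed_quotient = 0.4,
             growth_tau_cycles = 4, prephonation_delay_ms = 150,
             duration_s = 0.5, frame_width = 200, ...)
}

# vibrogram built directly from a width series (midline-symmetric edges)
vib_from_width <- function(width, fps = 2000, valid = NULL) {
  n <- length(width)
  vibrogram(frame = 0:(n - 1), left_px = 80 - width / 2,
            right_px = 80 + width / 2,
            valid = valid %||% rep(TRUE, n), fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# printed derived columns of the bundled reference token table, in fixture
# row order (soft, modal, loud per subject); transitions align to the
# arriving token
printed_resistance <- c(14.28571, 29.41176, 63.63636, 50.63291, 37.87879,
                        89.88764, 20, 13.63636, 41.17647, 40, 48.18182,
                        76.92308, 60, 112.5, 250, 35.38462, 53.84615,
                        93.33333)
printed_db_change <- c(11, 3, 13, 6, 6, 9, 10, 3, 9, 5, 11, 6)
printed_resistance_change <- c(15.12605, 34.2246, -12.7541, 52.00885,
                               -6.36364, 27.54011, 8.181818, 28.74126, 52.5,
                               137.5, 18.46154, 39.48718)
printed_per_db <- c(1.375095, 11.4082, -0.98109, 8.668142, -1.06061,
                    3.060012, 0.818182, 9.58042, 5.833333, 27.5, 1.678322,
                    6.581197)
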