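# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]]))
    .fixtures[[name]] <- suppressMessages(builder())
  .fixtures[[name]]
}

fx_cfg <- function() sim_config(n_trials = 30, seed = 101)

# complete session: behavior + LFP + mixed population + optotagging epoch
fx_session <- function() fixture("session", function() {
  simulate_session(fx_cfg(), truth = make_population_truth(n_units = 30,
                                                           seed = 7))
})

# binned substrate built from the generator's noiseless trajectory
fx_binned <- function() fixture("binned", function() {
  s <- fx_session()
  bin_session(s$truth$clean, s$truth$trials, s$truth$traversals, s$spikes,
              hemisphere = "right")
})

# small targeted population on a shared 25-trial session: a place unit, an
# untuned unit, a speed unit, and a direction unit
fx_targeted <- function() fixture("targeted", function() {
  cfg <- sim_config(n_trials = 25, seed = 303)
  tru <- dplyr::bind_rows(
    unit_truth("place4", "WS", 8,
               weights = list(linear_position = position_bump(4, 1.5))),
    unit_truth("flat", "WS", 8),
    unit_truth("speedy", "WS", 8, weights = list(speed = 0.5)),
    unit_truth("dirpref", "WS", 8,
               weights = list(run_phase = c(0.6, -0.6))))
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  s <- simulate_spikes(s, tru, cfg)
  b <- bin_session(s$truth$clean, s$truth$trials, s$truth$traversals,
                   s$spikes, hemisphere = "right")
  list(session = s, binned = b, cfg = cfg, truth = tru)
})

# noiseless straight-line tracking at constant speed
line_tracking <- function(n = 600, speed_cms = 30, fps = 20) {
  step <- speed_cms / fps
  tibble::tibble(frame_time_s = (0:(n - 1)) / fps,
                 head_x = (0:(n - 1)) * step, head_y = 0,
                 tail_x = (0:(n - 1)) * step - 15, tail_y = 0,
                 valid = TRUE)
}

expect_within <- function(x, lo, hi, label = deparse(substitute(x))) {
  expect_true(x >= lo && x <= hi,
              label = sprintf("%s = %g in [%g, %g]", label, x, lo, hi))
}
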