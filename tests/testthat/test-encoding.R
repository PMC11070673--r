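# Encoding models: cvR2 behavior, variable ranking, reduced models,
# stepwise inclusion, correlation structure, and the context model.

test_that("cvR2 is high for generative signal and near zero for noise", {
  fx <- fx_targeted()
  b <- fx$binned
  d <- build_design_matrix(b)
  strong <- fit_cv_poisson(d$X, b$counts[d$rows, "place4"])
  expect_gt(strong$cv_r2, 0.3)
  expect_lte(strong$cv_r2, 1)
  noise <- fit_cv_poisson(d$X, b$counts[d$rows, "flat"])
  expect_lt(noise$cv_r2, 0.05)
  expect_gte(noise$cv_r2, 0)
})

test_that("null cvR2 is centered near zero across simulated neurons", {
  fx <- fx_targeted()
  b <- fx$binned
  d <- build_design_matrix(b)
  n <- sum(d$rows)
  withr::with_seed(21, {
    cv <- replicate(40, {
      y <- rpois(n, 0.3)
      cpp_cv_poisson(d$X, y, 5)$cv_r2
    })
  })
  expect_lt(mean(cv), 0.01)
})

test_that("the single-variable scan ranks the generative variable first", {
  fx <- fx_targeted()
  sc_pos <- single_variable_scan(fx$binned, "place4")
  expect_equal(sc_pos$variable[1], "linear_position")
  sc_spd <- single_variable_scan(fx$binned, "speedy")
  expect_true(sc_spd$variable[1] %in% c("speed", "run_phase"))
  expect_gt(sc_spd$cv_r2[sc_spd$variable == "speed"], 0.01)
  # untuned: deterministic ranking with ties broken by canonical order
  sc1 <- single_variable_scan(fx$binned, "flat")
  sc2 <- single_variable_scan(fx$binned, "flat")
  expect_identical(sc1, sc2)
})

test_that("reduced models isolate the unique contribution", {
  fx <- fx_targeted()
  red <- reduced_model(fx$binned, "place4", "linear_position",
                       n_shifts = 100, seed = 17)
  expect_gt(red$delta_r2, 0.1)
  expect_true(red$significant)
  expect_lt(red$perm_p, 0.02)
  # untuned variable on the same neuron: no unique contribution
  red2 <- reduced_model(fx$binned, "place4", "turning", n_shifts = 100,
                        seed = 17)
  expect_lt(abs(red2$delta_r2), 0.02)
  # a variable absent from the model is an error
  expect_error(reduced_model(fx$binned, "place4", "trial_time",
                             n_shifts = 10),
               "not in the model")
})

test_that("delta r2 never exceeds the full-model cvR2 by more than noise", {
  fx <- fx_targeted()
  for (u in c("place4", "speedy")) {
    red <- reduced_model(fx$binned, u, "linear_position", n_shifts = 50,
                         seed = 3)
    expect_lte(red$delta_r2, red$cv_full + 0.01)
  }
})

test_that("full-model cvR2 is below the sum of single-variable cvR2 for
           correlated regressors", {
  # position and direction are intrinsically correlated on this task;
  # a unit driven by both shows sub-additive explained variance
  cfg <- sim_config(n_trials = 25, seed = 71)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  tru <- unit_truth("both", "WS", 8, weights = list(
    linear_position = position_bump(8, 1.2),
    run_phase = c(0.4, -0.4), speed = 0.3))
  s <- simulate_spikes(s, tru, cfg)
  b <- bin_session(s$truth$clean, s$truth$trials, s$truth$traversals,
                   s$spikes, "right")
  sc <- single_variable_scan(b, "both", ENCODING_VARIABLES)
  d <- build_design_matrix(b)
  full <- fit_cv_poisson(d$X, b$counts[d$rows, "both"])
  expect_lt(full$cv_r2, sum(sc$cv_r2))
})

test_that("stepwise inclusion keeps real variables and drops null candidates", {
  cfg <- sim_config(n_trials = 20, seed = 81)
  s0 <- simulate_behavior(cfg)
  s0 <- simulate_lfp(s0, cfg)
  tru <- make_encoding_population(n_units = 15, tuned_prob = 0.8,
                                  seed = 4)
  s <- simulate_spikes(s0, tru, cfg)
  b <- bin_session(s$truth$clean, s$truth$trials, s$truth$traversals,
                   s$spikes, "right")
  st <- stepwise_inclusion(b)
  expect_false(any(c("trial_time", "trial_history") %in% st$included))
  expect_true(all(c("linear_position", "run_phase") %in% st$included))
})

test_that("encoding correlations flag constructed dependence after Holm", {
  withr::with_seed(5, {
    n <- 60
    latent <- rexp(n, 10)
    tbl <- dplyr::bind_rows(
      tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                     variable = "linear_position",
                     delta_r2 = latent + rnorm(n, 0, 0.005)),
      tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                     variable = "run_phase",
                     delta_r2 = latent + rnorm(n, 0, 0.005)),
      tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                     variable = "speed",
                     delta_r2 = rexp(n, 10)))
  })
  out <- encoding_correlation_matrix(tbl, n_shuffle = 400, seed = 2)
  dep <- out[out$var1 == "linear_position" & out$var2 == "run_phase", ]
  expect_true(dep$significant)
  expect_gt(dep$r, 0.8)
  indep <- out[out$var2 == "speed" & out$var1 == "linear_position", ]
  expect_false(indep$significant)
})

test_that("the context model attributes variance to the right source", {
  cfg <- sim_config(n_trials = 25, seed = 91)
  s0 <- simulate_behavior(cfg)
  s0 <- simulate_lfp(s0, cfg)
  tru <- dplyr::bind_rows(
    unit_truth("ctx_dir", "FSPV", 12, weights = list(
      linear_position = position_bump(10, 0.9), run_phase = c(-0.4, 0.4))),
    unit_truth("ctx_speed", "WS", 10, weights = list(speed = 0.5)),
    unit_truth("ctx_null", "WS", 10))
  s <- simulate_spikes(s0, tru, cfg)
  b <- bin_session(s$truth$clean, s$truth$trials, s$truth$traversals,
                   s$spikes, "right")
  ctx <- context_model(b, n_shifts = 100, seed = 6)
  get <- function(u, v) ctx$delta_r2[ctx$unit_id == u & ctx$variable == v]
  expect_gt(get("ctx_dir", "position_with_direction"),
            get("ctx_dir", "speed"))
  expect_gt(get("ctx_speed", "speed"),
            get("ctx_speed", "position_with_direction"))
  expect_lt(max(abs(ctx$delta_r2[ctx$unit_id == "ctx_null"])), 0.03)
})
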