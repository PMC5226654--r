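test_that("background spike trains honour rate, refractory, and bounds", {
  set.seed(61)
  cfg <- background_config(n_units = 10, duration = 300)
  bg <- generate_background(cfg)
  ds <- bg$dataset
  expect_equal(length(ds$units), 10L)
  # latent rates bounded in (0, 2 * mean rate) by the erf sigmoid
  expect_true(all(bg$rates > 0 & bg$rates < 2 * cfg$mean_rate))
  rates <- vapply(ds$units, function(u)
    sum(ds$spikes$unit_id == u) / cfg$duration, 0)
  # refractory delay biases rates slightly below nominal: lambda/(1+lambda*tau)
  expect_lt(abs(mean(rates) - 5) / 5, 0.10)
  for (u in ds$units) {
    tt <- ds$spikes$time[ds$spikes$unit_id == u]
    expect_true(all(diff(tt) >= cfg$refractory - 1e-12))
  }
  expect_error(background_config(ar_coef = 1.01), "unstable")
})

test_that("embedded archetypes match their definitions", {
  set.seed(62)
  bg <- generate_background(background_config(n_units = 8, duration = 120))
  # type I: one occurrence = one synchronous spike per member
  e1 <- embed_assembly(bg$dataset, assembly_spec("I", c("u01", "u02", "u03"), 1))
  ins <- e1$dataset$spikes[e1$dataset$spikes$source == "A1", ]
  expect_equal(nrow(ins), 3L)
  expect_equal(length(unique(ins$time)), 1L)
  expect_setequal(ins$unit_id, c("u01", "u02", "u03"))

  # type II: identical frozen lag vector at every occurrence
  e2 <- embed_assembly(bg$dataset, assembly_spec("II", c("u04", "u05", "u06"), 20),
                       id = "A2")
  offs <- unlist(e2$truth$lag_offsets)
  expect_equal(offs[1], 0)
  expect_true(all(diff(offs) >= 0 & diff(offs) <= 0.1))
  spk2 <- e2$dataset$spikes[e2$dataset$spikes$source == "A2", ]
  for (j in 2:3) {
    tj <- sort(spk2$time[spk2$unit_id == c("u04", "u05", "u06")[j]])
    expect_equal(tj, sort(e2$truth$activations) + offs[j], tolerance = 1e-9)
  }

  # type V: member rate roughly doubles inside the 1-s windows
  e5 <- embed_assembly(bg$dataset, assembly_spec("V", c("u01", "u02"), 30),
                       id = "A5")
  spk5 <- e5$dataset$spikes
  in_win <- function(tt) any(tt >= e5$truth$activations &
                               tt <= e5$truth$activations + 1)
  member_spk <- spk5[spk5$unit_id %in% c("u01", "u02"), ]
  inside <- vapply(member_spk$time, in_win, TRUE)
  win_time <- 30 * 1  # occurrence windows may overlap; small correction ignored
  rate_in <- sum(inside) / (2 * win_time)
  expect_gt(rate_in, 7)
  expect_lt(rate_in, 13)

  # background spikes within +/- 15 ms of an assembly spike are erased
  for (u in c("u01", "u02", "u03")) {
    at <- ins$time[ins$unit_id == u]
    bgt <- e1$dataset$spikes$time[e1$dataset$spikes$unit_id == u &
                                    e1$dataset$spikes$source == "background"]
    if (length(at) && length(bgt))
      expect_gt(min(abs(outer(bgt, at, "-"))), 0.015)
  }
})

test_that("sorting-error corruption preserves counts and moves the stated fraction", {
  set.seed(63)
  bg <- generate_background(background_config(n_units = 5, duration = 60))
  ds <- bg$dataset
  expect_identical(corrupt_sorting(ds, 0)$spikes, ds$spikes)
  c3 <- corrupt_sorting(ds, 0.3)
  expect_equal(nrow(c3$spikes), nrow(ds$spikes))
  moved <- mean(grepl("sorterr", c3$spikes$source))
  expect_equal(moved, 0.3, tolerance = 0.01)
  # per-unit totals conserved overall
  expect_equal(sort(unique(c3$spikes$unit_id)) %in% ds$units, rep(TRUE, 5))
  c1 <- corrupt_sorting(ds, 1)
  expect_true(all(grepl("sorterr", c1$spikes$source)))
})

test_that("named scenarios have the documented structure and reproduce under a seed", {
  s1 <- generate_scenario("figure1", seed = 64, duration = 60,
                          n_occurrences = 10)
  expect_equal(length(s1$dataset$units), 50L)
  expect_equal(length(s1$truth$assemblies), 5L)
  members <- unlist(truth_partition(s1$truth))
  expect_equal(length(members), 25L)
  expect_equal(anyDuplicated(members), 0L)
  expect_gt(assembly_spike_fraction(s1$dataset), 0)
  s1b <- generate_scenario("figure1", seed = 64, duration = 60,
                           n_occurrences = 10)
  expect_identical(s1$dataset$spikes, s1b$dataset$spikes)

  # slow step-rate variant: exactly one high state of the scaled length
  s2 <- generate_scenario("step_rate", seed = 65, n_elementary = 2e4,
                          variant = "slow", coupled = TRUE)
  expect_equal(s2$truth$m, 1L)
  expect_equal(s2$truth$L, 1500)
  expect_identical(s2$truth$high_states_a, s2$truth$high_states_b)
  expect_equal(length(s2$truth$high_states_a), 1L)
  # binned at 100 elementary bins the pair is analyzable directly
  b <- bin_dataset(s2$dataset, 100)
  expect_equal(nrow(b$counts), 200L)

  # oscillation scenario embeds exactly the requested number of patterns
  s3 <- generate_scenario("oscillation", seed = 66, duration = 100,
                          patterns = TRUE, n_patterns = 20)
  expect_equal(length(s3$truth$assemblies[[1]]$activations), 20L)
  expect_equal(sum(s3$dataset$spikes$source == "pattern"), 40L)
})

test_that("oscillatory drive produces the nominal long-run rates", {
  set.seed(67)
  s <- generate_scenario("oscillation", duration = 600)
  ra <- sum(s$dataset$spikes$unit_id == "A") / 600
  rb <- sum(s$dataset$spikes$unit_id == "B") / 600
  expect_equal(ra, 5, tolerance = 3 * sqrt(5 / 600) / 5)
  # unit B is subject to clipping of negative instantaneous rates, which
  # biases its mean rate slightly above 2.5 Hz
  expect_gt(rb, 2.3)
  expect_lt(rb, 2.9)
})
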