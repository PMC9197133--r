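test_that("voltage transform maps reset to origin and is exactly invertible", {
  p <- d1_params(); cfg <- default_cfg()
  expect_equal(voltage_to_loihi(-70, p, cfg), 0)
  expect_equal(voltage_to_loihi(-43, p, cfg), 270000)
  expect_equal(voltage_to_loihi(-69.9999, p, cfg), 1, tolerance = 1e-9)
  expect_equal(voltage_from_loihi(0, p, cfg), -70)
  expect_equal(voltage_from_loihi(270000, p, cfg), -43)
  expect_equal(voltage_from_loihi(voltage_to_loihi(-55.5, p, cfg), p, cfg),
               -55.5)
  # round trip is the identity for arbitrary Vs and V
  set.seed(7)
  for (i in 1:20) {
    cfg_i <- mapping_config(Vs = 10^runif(1, -6, -2))
    V <- runif(10, -90, -30)
    expect_equal(voltage_from_loihi(voltage_to_loihi(V, p, cfg_i), p, cfg_i),
                 V, tolerance = 1e-12)
  }
})

test_that("voltage decay word follows the 12-bit linear correspondence", {
  cfg <- default_cfg()
  expect_equal(compute_voltage_decay(25, cfg)$delta, 164)  # 4096/25 = 163.84
  expect_equal(compute_voltage_decay(22, cfg)$delta, 186)  # 4096/22 = 186.18
  full <- compute_voltage_decay(1, cfg)
  expect_equal(full$delta, 4096)
  expect_equal(full$stored, 0L)  # stored 0 denotes full decay
  # floor policy truncates instead of rounding
  expect_equal(compute_voltage_decay(25, mapping_config(rounding = "floor"))$delta,
               163)
})

test_that("representability holds exactly on [dt, 4096*dt]", {
  expect_error(compute_voltage_decay(50, mapping_config(dt = 0.01)),
               "not representable")
  expect_error(compute_voltage_decay(0.5, default_cfg()), "below one step")
  expect_error(compute_voltage_decay(5000, default_cfg()), "2\\^12")
  expect_equal(max_representable_tau(default_cfg()), 4096)
  expect_equal(max_representable_tau(mapping_config(dt = 0.01)), 40.96)
  # boundary values succeed
  expect_equal(compute_voltage_decay(4096, default_cfg())$delta, 1)
  expect_equal(compute_voltage_decay(40.96, mapping_config(dt = 0.01))$delta, 1)
})

test_that("decay word is monotone in tau_v and dt", {
  cfg <- default_cfg()
  taus <- seq(2, 400, by = 7)
  deltas <- vapply(taus, function(tv) compute_voltage_decay(tv, cfg)$delta,
                   numeric(1))
  expect_true(all(diff(deltas) <= 0))
  dts <- c(0.1, 0.5, 1, 2, 5)
  deltas_dt <- vapply(dts, function(dt)
    compute_voltage_decay(25, mapping_config(dt = dt))$delta, numeric(1))
  expect_true(all(diff(deltas_dt) >= 0))
})

test_that("current decay word tracks the exponential kernel", {
  cfg <- default_cfg()
  for (ts in c(1.5, 2, 5, 20)) {
    du <- compute_current_decay(ts, cfg)$delta
    expect_lt(abs((4096 - du) / 4096 - exp(-1 / ts)), 1 / 4096)
  }
  expect_error(compute_current_decay(1e5, cfg), "not representable")
})

test_that("threshold maps through the 17-high-bit quantization", {
  p <- d1_params(); cfg <- default_cfg()
  th <- map_threshold(p, cfg)
  expect_equal(th$theta_mant, 4219)   # 270000/64 = 4218.75
  expect_equal(th$theta_eff, 270016)
  one <- neuron_params(25, 170, -70, -70, -70 + 1e-4 * 64)
  expect_equal(map_threshold(one, cfg)$theta_mant, 1)
  expect_equal(map_threshold(p, mapping_config(Vs = 1e-5))$theta_eff, 2700032)
  expect_error(map_threshold(p, mapping_config(Vs = 1e-6)),
               "threshold overflow")
  # nearest-rounding quantization error bounded by half a quantum (2^5)
  set.seed(11)
  for (i in 1:30) {
    pp <- neuron_params(25, 170, -70, -70, runif(1, -60, -20))
    err <- map_threshold(pp, cfg)$theta_eff - (pp$Theta - pp$Vr) / cfg$Vs
    expect_lte(abs(err), 32)
  }
})

test_that("bias encoder picks the smallest exponent and bounds its error", {
  cfg <- default_cfg()
  b1 <- map_bias(d1_params(), cfg)
  expect_equal(b1$bias_mant, 2938)  # 11750.2 / 2^2, nearest
  expect_equal(b1$bias_exp, 2L)
  expect_equal(b1$bias_eff, 11752)
  b0 <- map_bias(d2_params(), cfg)  # zero current, EL = Vr
  expect_equal(c(b0$bias_mant, b0$bias_exp, b0$bias_eff), c(0, 0, 0))
  leak <- neuron_params(25, 170, EL = -70, Vr = -75, Theta = -43, Ie = 0)
  b2 <- map_bias(leak, cfg)  # (5/25)/1e-4 = 2000 levels/step, fits exp 0
  expect_equal(c(b2$bias_mant, b2$bias_exp), c(2000, 0))
  expect_error(map_bias(neuron_params(25, 170, -70, -70, -43, Ie = 1e7), cfg),
               "bias overflow")
  # |effective - target| <= 2^(exp-1) under nearest rounding
  set.seed(3)
  for (i in 1:40) {
    pp <- neuron_params(runif(1, 5, 100), runif(1, 100, 400), -70, -70, -43,
                        Ie = runif(1, -2000, 2000))
    bb <- map_bias(pp, cfg)
    expect_lte(abs(bb$bias_eff - bb$target), max(2^(bb$bias_exp - 1), 0.5))
  }
})

test_that("spike times bin by floor and merge per-step multiplicity", {
  expect_equal(scale_spike_times(446, default_cfg())$step, 446L)
  expect_equal(scale_spike_times(446, mapping_config(dt = 0.1))$step, 4460L)
  expect_equal(scale_spike_times(446, mapping_config(dt = 10))$step, 44L)
  merged <- scale_spike_times(c(53, 53.2, 53.9, 88), default_cfg())
  expect_equal(merged$step, c(53L, 88L))
  expect_equal(merged$count, c(3L, 1L))
  expect_error(scale_spike_times(-1, default_cfg()), "non-negative")
})

test_that("weight scaling to levels inverts through current_from_levels", {
  p <- d2_params(); cfg <- default_cfg()
  w_int <- weight_to_levels(100, p, cfg)
  expect_equal(w_int, 5882)  # 100 / (170 * 1e-4)
  expect_equal(current_from_levels(w_int, p, cfg), 99.994)
})

test_that("full compartment mapping assembles all quantized words", {
  comp <- loihi_compartment(d1_params(), default_cfg())
  expect_equal(comp$delta_v, 164)
  expect_equal(comp$delta_u, 1612)  # 4096*(1 - exp(-1/2))
  expect_equal(comp$theta_eff, 270016)
  expect_equal(comp$bias_eff, 11752)
  expect_lt(comp$theta_eff, 2^23)
})
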