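test_that("single step applies floor decay, bias, current and strict threshold", {
  comp <- synthetic_comp(delta_v = 164, bias_eff = 0)
  expect_equal(loihi_step(1000, 0, comp)$v, 959)  # floor(1000*3932/4096)
  # stored full decay wipes the state: v' = b
  full <- synthetic_comp(delta_v = 4096, bias_eff = 5)
  expect_equal(loihi_step(123456, 0, full)$v, 5)
  # strict inequality at the threshold boundary
  at <- synthetic_comp(delta_v = 4096, bias_eff = 270016, theta_eff = 270016)
  expect_false(loihi_step(0, 0, at)$spiked)
  expect_equal(loihi_step(0, 0, at)$v, 270016)
  above <- synthetic_comp(delta_v = 4096, bias_eff = 270017,
                          theta_eff = 270016)
  expect_true(loihi_step(0, 0, above)$spiked)
  expect_equal(loihi_step(0, 0, above)$v, 0)
})

test_that("step equivalence with an independent integer oracle", {
  oracle_step <- function(v, u, comp, inp) {
    u2 <- (u * (4096 - comp$delta_u)) %/% 4096
    u2 <- u2 + inp
    if (u2 > 8388607) u2 <- 8388607 else if (u2 < -8388607) u2 <- -8388607
    v2 <- (v * (4096 - comp$delta_v)) %/% 4096
    v2 <- v2 + comp$bias_eff + u2
    if (v2 > 8388607) v2 <- 8388607 else if (v2 < -8388607) v2 <- -8388607
    sp <- v2 > comp$theta_eff
    if (sp) v2 <- 0
    list(v = v2, u = u2, spiked = sp)
  }
  set.seed(42)
  n <- 1e5
  vs <- sample.int(2^24 - 1, n, replace = TRUE) - 2^23  # in (-2^23, 2^23)
  us <- sample.int(2^24 - 1, n, replace = TRUE) - 2^23
  dvs <- sample.int(4096, n, replace = TRUE)
  dus <- sample.int(4096, n, replace = TRUE)
  bs <- sample.int(2^19, n, replace = TRUE) - 2^18
  ths <- sample.int(2^17, n, replace = TRUE) * 64 - 64
  inps <- sample.int(2^16, n, replace = TRUE) - 2^15
  for (i in seq_len(n)) {
    comp <- synthetic_comp(delta_v = dvs[i], delta_u = dus[i],
                           theta_eff = ths[i], bias_eff = bs[i])
    got <- loihi_step(vs[i], us[i], comp, inps[i])
    want <- oracle_step(vs[i], us[i], comp, inps[i])
    if (got$v != want$v || got$u != want$u || got$spiked != want$spiked) {
      fail(sprintf("state %d diverged: v %d/%d u %d/%d", i,
                   got$v, want$v, got$u, want$u))
      break
    }
  }
  succeed()
})

test_that("per-step truncation stays below one current and two voltage levels", {
  set.seed(9)
  for (i in 1:500) {
    comp <- synthetic_comp(delta_v = sample.int(4096, 1),
                           delta_u = sample.int(4096, 1),
                           theta_eff = 2^22, bias_eff = sample.int(4000, 1))
    v <- sample.int(2^22, 1); u <- sample.int(2^20, 1)
    got <- loihi_step(v, u, comp, 0, threshold = FALSE)
    u_real <- u * (4096 - comp$delta_u) / 4096
    v_real <- v * (4096 - comp$delta_v) / 4096 + comp$bias_eff + u_real
    expect_lt(abs(got$u - u_real), 1)
    expect_lt(abs(got$v - v_real), 2)
  }
})

test_that("mapped bias-driven compartment fires tonically near the reference", {
  comp <- loihi_compartment(d1_params())
  run <- simulate_emulator(comp, n_steps = 500)
  expect_gte(length(run$spike_steps), 7)
  expect_lte(abs(run$spike_steps[1] - 63), 2)
  expect_true(all(run$v_trace < comp$theta_eff))  # reset precedes recording
  expect_equal(run$n_saturated, 0L)
})

test_that("quiet compartment stays at zero; constant drive finds its fixed point", {
  quiet <- synthetic_comp(delta_v = 164, bias_eff = 0)
  expect_true(all(simulate_emulator(quiet, n_steps = 100)$v_trace == 0))
  # subthreshold drive: trace settles within truncation reach of b*4096/dv
  p <- neuron_params(25, 170.21, -70, -70, -43, Ie = 150)
  comp <- loihi_compartment(p)
  run <- simulate_emulator(comp, n_steps = 400)
  expect_lt(abs(run$v_trace[400] - steady_state(comp)), 4096 / comp$delta_v + 2)
})

test_that("real-valued fixed point diagnostics", {
  comp <- loihi_compartment(d1_params())
  expect_equal(steady_state(comp), 11752 * 4096 / 164, tolerance = 1e-12)
  expect_gt(steady_state(comp), comp$theta_eff)  # predicts tonic firing
  expect_equal(steady_state(synthetic_comp(delta_v = 164, bias_eff = 0)), 0)
  expect_equal(steady_state(synthetic_comp(delta_v = 4096, bias_eff = 77)), 77)
})

test_that("runs are deterministic and spikes equal reset events", {
  comp <- loihi_compartment(d1_params())
  a <- simulate_emulator(comp, n_steps = 500)
  b <- simulate_emulator(comp, n_steps = 500)
  expect_identical(a$v_trace, b$v_trace)
  expect_identical(a$spike_steps, b$spike_steps)
  # every spike is a reset event, and only spike steps reset from firing
  expect_true(all(a$v_trace[a$spike_steps] == 0))
  expect_equal(sum(a$v_trace == 0 & seq_len(500) > 1), length(a$spike_steps))
})

test_that("overflow saturates (no wraparound) and is counted", {
  comp <- synthetic_comp(delta_v = 1, bias_eff = 2^22, theta_eff = 2^23 - 64)
  run <- simulate_emulator(comp, n_steps = 20, threshold = FALSE)
  expect_equal(max(run$v_trace), 2^23 - 1)
  expect_true(all(run$v_trace <= 2^23 - 1))
  expect_gt(run$n_saturated, 0)
})

test_that("inverse-mapped emulator approaches the real Euler trajectory as Vs shrinks", {
  p <- neuron_params(25, 170.21, -70, -70, -43, Ie = 150)
  maxdiff <- vapply(c(1e-3, 1e-5), function(vs) {
    cfg <- mapping_config(Vs = vs)
    comp <- loihi_compartment(p, cfg)
    run <- simulate_emulator(comp, n_steps = 300, threshold = FALSE)
    v_real <- 0; euler <- numeric(300)
    for (k in 1:300) {
      v_real <- v_real * (1 - comp$delta_v / 4096) + comp$bias_target
      euler[k] <- v_real * vs + p$Vr
    }
    max(abs(voltage_from_loihi(run$v_trace, p, cfg) - euler))
  }, numeric(1))
  expect_gt(maxdiff[1] / maxdiff[2], 10)  # error shrinks with the level size
})
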