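test_that("ODE solution matches the linear closed form", {
  toy <- toy_linear_model(k1 = 2, k2 = 0.1)
  tr <- integrate_ode(toy, pattern = constant_signal(1),
                      sample_times = seq(0, 300, by = 1))
  expect_equal(tr$output, (2 / 0.1) * (1 - exp(-0.1 * tr$times)),
               tolerance = 1e-6)
})

test_that("conserved totals stay constant along trajectories", {
  for (mid in c("M1", "M2", "M3", "M4")) {
    m <- hub_model(mid)
    tr <- integrate_ode(m, pattern = signal_pattern("S1"))
    for (pool in m$pools) {
      tot <- rowSums(tr$states[, pool$members, drop = FALSE])
      expect_equal(tot, rep(pool$total, length(tot)),
                   tolerance = 1e-6)
    }
  }
})

test_that("a single sample time returns the initial state", {
  m <- hub_model("M1")
  tr <- integrate_ode(m, pattern = signal_pattern("S1"), sample_times = 0)
  expect_equal(tr$states[1, ], m$init)
})

test_that("tightening solver tolerances barely changes the output", {
  for (mid in c("M1", "M2", "M3", "M4")) {
    m <- hub_model(mid)
    a <- integrate_ode(m, pattern = signal_pattern("S1"),
                       rtol = 1e-8, atol = 1e-8)$output
    b <- integrate_ode(m, pattern = signal_pattern("S1"),
                       rtol = 1e-9, atol = 1e-9)$output
    expect_lt(max(abs(a - b)) / max(abs(b)), 1e-4)
  }
})

test_that("integration failure raises a typed condition carrying the set id", {
  m <- hub_model("M1")
  # an exhausted step budget is the deterministic route to solver failure
  cond <- tryCatch(
    integrate_ode(m, pattern = signal_pattern("S1"),
                  sample_times = seq(0, 300, 30), maxsteps = 3,
                  set_id = "bad-set"),
    hubsens_integration_error = function(e) e)
  expect_s3_class(cond, "hubsens_integration_error")
  expect_identical(cond$set_id, "bad-set")

  # a genuinely pathological parameter set fails at study settings too
  p <- stats::setNames(exp(failing_m1_logp), m$param_names)
  cond2 <- tryCatch(
    { for (pat in signal_patterns())
        integrate_ode(m, p, pat, sample_times = seq(0, 300, 30),
                      maxsteps = 100)
      NULL },
    hubsens_integration_error = function(e) e)
  expect_s3_class(cond2, "hubsens_integration_error")
})

test_that("CLE trajectories are reproducible under a fixed seed", {
  m <- hub_model("M1")
  a <- simulate_cle(m, pattern = signal_pattern("S1"), seed = 31)
  b <- simulate_cle(m, pattern = signal_pattern("S1"), seed = 31)
  d <- simulate_cle(m, pattern = signal_pattern("S1"), seed = 32)
  expect_identical(a$states, b$states)
  expect_false(identical(a$states, d$states))
})

test_that("zero diffusion reduces Euler-Maruyama to fixed-step Euler", {
  toy <- toy_linear_model(k1 = 2, k2 = 0.1)
  dt <- 0.05
  tr <- simulate_cle(toy, pattern = constant_signal(1), dt = dt,
                     sample_times = seq(0, 10, by = 1), seed = 1,
                     noise_scale = 0)
  # independent fixed-step Euler in R
  x <- 0
  euler <- c(0, vapply(seq_len(10 / dt), function(i) {
    x <<- x + (2 - 0.1 * x) * dt
    x
  }, 0))
  expect_equal(tr$output, euler[seq(1, length(euler), by = 1 / dt)],
               tolerance = 1e-12)
})

test_that("Ornstein-Uhlenbeck moments match the closed forms", {
  k <- 0.2; sigma <- 0.5; x0 <- 3
  ou <- ou_model(k, sigma, x0)
  set.seed(11)
  enc <- hubsens:::encode_model(ou, ou$params, constant_signal(0))
  st <- c(1, 5)
  n <- 2000
  reps <- .Call("C_cle_ensemble", enc, x0, 0.01, st, 1,
                hubsens:::boundary_code("none"), as.integer(n), 1L, 10L,
                PACKAGE = "hubsens")
  m_th <- x0 * exp(-k * st)
  v_th <- sigma^2 / (2 * k) * (1 - exp(-2 * k * st))
  m_obs <- colMeans(reps)
  v_obs <- apply(reps, 2, stats::var)
  se_m <- sqrt(v_th / n)
  se_v <- v_th * sqrt(2 / n)
  expect_true(all(abs(m_obs - m_th) < 4 * se_m))
  expect_true(all(abs(v_obs - v_th) < 4 * se_v))
})

test_that("halving dt leaves ensemble means within Monte-Carlo error", {
  m <- hub_model("M1")
  pat <- signal_pattern("S9")
  enc <- hubsens:::encode_model(m, m$params, pat)
  st <- c(60, 180, 300)
  n <- 300L
  run <- function(dt, seed) {
    set.seed(seed)
    .Call("C_cle_ensemble", enc, unname(m$init), dt, st, 1,
          hubsens:::boundary_code("clip"), n, 2L, 10L, PACKAGE = "hubsens")
  }
  a <- run(0.02, 5)
  b <- run(0.01, 6)
  se <- sqrt(apply(a, 2, stats::var) / n + apply(b, 2, stats::var) / n)
  expect_true(all(abs(colMeans(a) - colMeans(b)) < 4 * se))
})

test_that("CLE ensemble mean tracks the ODE as noise shrinks", {
  m <- hub_model("M1")
  pat <- signal_pattern("S9")
  ode <- integrate_ode(m, pattern = pat,
                       sample_times = seq(30, 300, 30))$output
  set.seed(21)
  enc <- hubsens:::encode_model(m, m$params, pat)
  n <- 400L
  reps <- .Call("C_cle_ensemble", enc, unname(m$init), 0.01,
                seq(30, 300, 30), 0.3, hubsens:::boundary_code("clip"),
                n, 2L, 10L, PACKAGE = "hubsens")
  se <- sqrt(apply(reps, 2, stats::var) / n)
  expect_true(all(abs(colMeans(reps) - ode) < 4 * se + 0.01 * max(ode)))
})

test_that("control data summarise the replicate ensemble correctly", {
  ctrl <- unit_control_m1()
  expect_length(ctrl$patterns, 10)
  expect_identical(ctrl$sample_times, seq(30, 300, by = 30))
  for (p in ctrl$patterns) {
    expect_equal(p$se, p$sd / sqrt(ctrl$n_replicates))
    expect_equal(p$norm_mean, sqrt(sum(p$mean^2)))
  }
  # deterministic under the same root seed
  again <- generate_control_data(hub_model("M1"), n_replicates = 50,
                                 seed = 7)
  expect_identical(ctrl$patterns, again$patterns)
})

test_that("noise-free control data collapse onto the ODE solution", {
  m <- hub_model("M1")
  ctrl <- generate_control_data(m, n_replicates = 5, seed = 1,
                                noise_scale = 0, dt = 0.01)
  for (pid in c("S1", "S9")) {
    ode <- integrate_ode(m, pattern = signal_pattern(pid),
                         sample_times = seq(30, 300, 30))$output
    expect_equal(ctrl$patterns[[pid]]$mean, ode, tolerance = 1e-3)
    expect_equal(ctrl$patterns[[pid]]$sd, rep(0, 10))
  }
})

test_that("dt must divide the sampling interval", {
  m <- hub_model("M1")
  expect_error(simulate_cle(m, pattern = signal_pattern("S1"), dt = 0.7,
                            sample_times = c(30, 60)),
               "divide")
})
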