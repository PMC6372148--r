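test_that("the four motifs expose the documented reactions, pools and output", {
  m1 <- hub_model("M1")
  expect_setequal(m1$labels, c("A", "D"))
  expect_length(m1$pools, 1)

  m2 <- hub_model("M2")
  expect_true("R" %in% m2$labels)
  expect_setequal(m2$labels, c("A", "D", "R"))

  m3 <- hub_model("M3")
  expect_true("FBA" %in% m3$labels)

  m4 <- hub_model("M4")
  expect_true(all(c("FFA", "FFR", "D", "DS") %in% m4$labels))

  for (mid in c("M1", "M2", "M3", "M4")) {
    m <- hub_model(mid)
    expect_identical(m$output, "Xa")
    # each parameter belongs to exactly one reaction
    expect_false(anyDuplicated(m$param_names) > 0)
    # initial state honours the conserved totals
    for (pool in m$pools)
      expect_equal(sum(m$init[pool$members]), pool$total)
  }

  expect_error(hub_model("M9"), "unknown model id")
})

test_that("rate laws match independent scalar formulas on random states", {
  # hand-written oracle for every reaction of every motif
  oracle <- list(
    M1 = function(st, s, p) c(
      A = p[["k1"]] * s * st[["X"]] / (p[["km1"]] + st[["X"]]),
      D = p[["k2a"]] * st[["Xa"]]),
    M2 = function(st, s, p) c(
      A = p[["k1"]] * s * st[["X"]] / (p[["km1"]] + st[["X"]]),
      D = p[["k2a"]] * st[["Xa"]],
      R = p[["k3"]] * st[["Xr"]] / (p[["km3"]] + st[["Xr"]])),
    M3 = function(st, s, p) c(
      A = p[["k1"]] * s * st[["X"]] / (p[["km1"]] + st[["X"]]),
      D = p[["k2a"]] * st[["Xa"]],
      DS = p[["k2b"]] * st[["Ya"]] * st[["Xa"]] / (p[["km2"]] + st[["Xa"]]),
      FBA = p[["k3"]] * st[["Xa"]] * st[["Y"]] / (p[["km3"]] + st[["Y"]]),
      FBR = p[["k4"]] * st[["Ya"]]),
    M4 = function(st, s, p) c(
      A = p[["k1"]] * s * st[["X"]] / (p[["km1"]] + st[["X"]]),
      D = p[["k2a"]] * st[["Xa"]],
      DS = p[["k2b"]] * st[["Ya"]] * st[["Xa"]] / (p[["km2"]] + st[["Xa"]]),
      FFA = p[["k3"]] * s * st[["Y"]] / (p[["km3"]] + st[["Y"]]),
      FFR = p[["k4"]] * st[["Ya"]]))

  set.seed(1)
  for (mid in names(oracle)) {
    m <- hub_model(mid)
    for (rep in 1:5) {
      st <- stats::setNames(stats::runif(length(m$species), 0, 100),
                            m$species)
      s <- stats::runif(1, 0, 1)
      a <- evaluate_rates(m, st, s)
      expect_equal(a, oracle[[mid]](st, s, m$params), tolerance = 1e-12)
      expect_true(all(a >= 0))
    }
  }
})

test_that("rate-law structure: zero substrate, half-saturation, linearity", {
  m <- hub_model("M1")
  p <- m$params
  # zero substrate kills the reaction
  a0 <- evaluate_rates(m, c(X = 0, Xa = 0), s = 1)
  expect_equal(unname(a0), c(0, 0))
  # Michaelis-Menten at S = km is half the saturating rate
  a <- evaluate_rates(m, c(X = p[["km1"]], Xa = 0), s = 1)
  expect_equal(a[["A"]], p[["k1"]] * 1 / 2)
  # mass action is linear in its rate constant
  p2 <- p; p2[["k2a"]] <- 2 * p[["k2a"]]
  st <- c(X = 10, Xa = 40)
  expect_equal(evaluate_rates(m, st, 1, p2)[["D"]],
               2 * evaluate_rates(m, st, 1, p)[["D"]])
})

test_that("stoichiometry conserves every pool for any rate vector", {
  for (mid in c("M1", "M2", "M3", "M4")) {
    m <- hub_model(mid)
    for (pool in m$pools) {
      w <- as.numeric(m$species %in% pool$members)
      expect_equal(unname(w %*% m$stoich), matrix(0, 1, ncol(m$stoich)))
    }
  }
})

test_that("compiled and R rate evaluation agree", {
  set.seed(2)
  for (mid in c("M1", "M3")) {
    m <- hub_model(mid)
    pat <- signal_pattern("S1")
    enc <- hubsens:::encode_model(m, m$params, pat)
    for (rep in 1:5) {
      st <- stats::runif(length(m$species), 0, 100)
      s <- stats::runif(1)
      a_c <- .Call("C_rates_eval", enc, st, s, PACKAGE = "hubsens")
      a_r <- evaluate_rates(m, stats::setNames(st, m$species), s)
      expect_equal(unname(a_r), a_c, tolerance = 1e-12)
    }
  }
})

test_that("invalid states and parameters are rejected", {
  m <- hub_model("M1")
  expect_error(evaluate_rates(m, c(X = -1, Xa = 0), 1), "negative")
  p <- m$params; p[["k1"]] <- 0
  expect_error(evaluate_rates(m, c(X = 1, Xa = 1), 1, p), "non-positive")
  expect_error(evaluate_rates(m, c(X = 1, Xa = 1), -0.5), "signal")
})

test_that("user-defined networks go through the extension point", {
  toy <- toy_linear_model()
  expect_s3_class(toy, "hub_model")
  expect_equal(toy$param_names, c("k1", "k2"))
  a <- evaluate_rates(toy, c(Xa = 5), s = 2)
  expect_equal(unname(a), c(2 * 2, 0.1 * 5))
  # duplicate parameter names are a configuration error
  expect_error(define_hub_model("bad", "X", 1, list(
    list(label = "r1", type = "zero_order", to = "X", k_name = "k",
         k_value = 1),
    list(label = "r2", type = "mass_action", from = "X", substrate = "X",
         k_name = "k", k_value = 1)), output = "X"),
    "exactly one reaction")
})
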