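test_that("cosine fitness scores the worked examples correctly", {
  expect_equal(cosine_fitness(list(c(1, 2)), list(c(2, 4))), 0)
  expect_equal(cosine_fitness(list(c(1, 0, 0)), list(c(0, 1, 0))), 1)
  expect_equal(cosine_fitness(list(c(1, 1)), list(c(1, 0))), 0.5)
})

test_that("cosine fitness is scale invariant and bounded", {
  set.seed(4)
  for (rep in 1:20) {
    n_pat <- sample(1:10, 1)
    sim <- replicate(n_pat, stats::rnorm(10), simplify = FALSE)
    ctrl <- replicate(n_pat, stats::rnorm(10), simplify = FALSE)
    f <- cosine_fitness(sim, ctrl)
    expect_gte(f, 0)
    expect_lte(f, n_pat)
    c1 <- stats::runif(1, 0.01, 100)
    scaled <- lapply(sim, function(v) c1 * v)
    expect_equal(cosine_fitness(scaled, ctrl), f, tolerance = 1e-12)
  }
})

test_that("degenerate vectors are handled per the contract", {
  expect_warning(f <- cosine_fitness(list(c(0, 0)), list(c(1, 1))),
                 "zero-norm")
  expect_equal(f, 1)
  expect_error(cosine_fitness(list(c(1, 1)), list(c(0, 0))),
               "control")
})

test_that("scaling factor is the norm ratio", {
  expect_equal(scaling_factor(c(1, 2), 2 * c(1, 2)), 2)
  v <- c(0.3, -0.4, 1.2)
  u <- v / sqrt(sum(v^2))
  expect_equal(scaling_factor(u, c(7.3, 0, 0)), 7.3)
  set.seed(5)
  for (rep in 1:10) {
    s <- stats::rnorm(10); cc <- stats::rnorm(10)
    a <- scaling_factor(s, cc)
    expect_equal(a * sqrt(sum(s^2)), sqrt(sum(cc^2)))
  }
  expect_error(scaling_factor(rep(0, 5), 1:5),
               class = "hubsens_scaling_error")
})

# a hand-made control object with unit SD bands around given means
fake_control <- function(means, sd = 1) {
  per <- lapply(means, function(m)
    list(mean = m, sd = rep(sd, length(m)),
         se = rep(sd, length(m)) / sqrt(100),
         norm_mean = sqrt(sum(m^2))))
  structure(list(model_id = "M1", n_replicates = 100,
                 sample_times = seq(30, by = 30,
                                    length.out = length(means[[1]])),
                 patterns = per, dt = 0.01, rng_seed = 1, noise_scale = 1),
            class = "control_data")
}

test_that("classification follows the strict all-points band rule", {
  means <- list(S1 = c(5, 8, 6), S2 = c(2, 3, 1))
  ctrl <- fake_control(means, sd = 1)

  # exactly on the mean (after alpha scaling): positive
  rep1 <- classify(lapply(means, function(m) m / 3), ctrl)
  expect_identical(rep1$label, "positive")
  expect_equal(unname(rep1$alpha_per_pattern), c(3, 3))
  expect_equal(rep1$fitness, 0, tolerance = 1e-12)

  # same norm (alpha = 1) but wrong shape: out of band in one pattern only
  off <- means
  off$S2 <- c(2, 1, 3)  # permuted components keep the norm, break the band
  rep2 <- classify(off, ctrl)
  expect_identical(rep2$label, "negative")
  expect_true(rep2$pattern_pass_mask[["S1"]])
  expect_false(rep2$pattern_pass_mask[["S2"]])

  # excluded sets are counted in neither class
  rep3 <- classify(list(), ctrl, excluded = TRUE, set_id = "x")
  expect_identical(rep3$label, "excluded")
})

test_that("classification is monotone in the band width", {
  means <- list(S1 = c(5, 8, 6))
  sim <- list(S1 = c(5.5, 7.4, 6.3))
  labels <- vapply(c(0.05, 0.2, 0.6, 2), function(s) {
    classify(sim, fake_control(means, sd = s))$label
  }, "")
  # once positive at some band, positive at every wider band
  first_pos <- match("positive", labels)
  expect_false(is.na(first_pos))
  expect_true(all(labels[first_pos:length(labels)] == "positive"))
  expect_identical(labels[1], "negative")
})

test_that("the generating parameter set reproduces its own control data", {
  ctrl <- unit_control_m1()
  rep <- hubsens:::evaluate_candidate(hub_model("M1"),
                                      hub_model("M1")$params, ctrl,
                                      band = "sd")
  expect_identical(rep$label, "positive")
  expect_lt(rep$fitness, 0.05)
})

test_that("integration failures are excluded, not classified", {
  m <- hub_model("M1")
  ctrl <- unit_control_m1()
  rep <- hubsens:::evaluate_candidate(m, m$params, ctrl, set_id = "bad",
                                      maxsteps = 3)
  expect_identical(rep$label, "excluded")
  expect_true(rep$excluded)
})
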