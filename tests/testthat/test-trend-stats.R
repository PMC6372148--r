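test_that("PCA recovers rank-1 structure and isotropic symmetry", {
  # points on a line: first component carries all variance
  set.seed(8)
  t <- stats::rnorm(200)
  line <- cbind(2 * t, -t)
  p <- hub_pca(line, standardize = FALSE)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-12)

  # isotropic 2-D Gaussian: both components explain ~ half
  iso <- matrix(stats::rnorm(20000), ncol = 2)
  p2 <- hub_pca(iso, standardize = FALSE)
  expect_equal(p2$explained_variance_ratio,
               c(0.5, 0.5), tolerance = 0.03)
})

test_that("PCA satisfies the reconstruction identity and conventions", {
  set.seed(9)
  x <- matrix(stats::rnorm(60), ncol = 3) %*%
    matrix(c(1, 0.5, 0, 0, 1, 0.3, 0.2, 0, 1), 3)
  for (std in c(TRUE, FALSE)) {
    p <- hub_pca(x, standardize = std)
    recon <- p$scores %*% t(p$loadings)
    if (std) recon <- sweep(recon, 2, p$scale, `*`)
    recon <- sweep(recon, 2, p$center, `+`)
    expect_equal(recon, x, tolerance = 1e-10, ignore_attr = TRUE)
    # non-increasing explained variance summing to one
    expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
    expect_equal(sum(p$explained_variance_ratio), 1)
    # sign convention: the largest-magnitude loading is positive
    for (j in seq_len(ncol(p$loadings))) {
      v <- p$loadings[, j]
      expect_gte(v[which.max(abs(v))], 0)
    }
    # components are orthonormal
    expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

make_table <- function(values) {
  # values: named list set_id -> named reaction vector (one pattern "S3")
  df <- do.call(rbind, lapply(names(values), function(id)
    data.frame(set_id = id, label = "positive", pattern = "S3",
               reaction = names(values[[id]]), q = 100,
               s_log = unname(values[[id]]), stringsAsFactors = FALSE)))
  synthetic_sens_table(df)
}

test_that("z-scores standardise each set across its reactions", {
  tab <- make_table(list(a = c(A = 1, B = 2, C = 3)))
  z <- zscore_across_reactions(tab, "S3", measure = "signed")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))

  tab2 <- make_table(list(a = c(A = 0.1, B = 0.7)))
  z2 <- zscore_across_reactions(tab2, "S3", measure = "signed")
  expect_equal(unname(z2["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # population SD variant
  z2p <- zscore_across_reactions(tab2, "S3", measure = "signed",
                                 sd_type = "population")
  expect_equal(unname(z2p["a", ]), c(-1, 1))

  # location invariance and row moments on random tables
  set.seed(10)
  vals <- stats::setNames(stats::rnorm(5), LETTERS[1:5])
  za <- zscore_across_reactions(make_table(list(s = vals)), "S3",
                                measure = "signed")
  zb <- zscore_across_reactions(make_table(list(s = vals + 7)), "S3",
                                measure = "signed")
  expect_equal(za, zb, tolerance = 1e-10)
  expect_lt(abs(mean(za)), 1e-12)
  expect_equal(stats::sd(za), 1, tolerance = 1e-12)

  # all-tied reactions give a flagged row of zeros
  zt <- zscore_across_reactions(make_table(list(s = c(A = 1, B = 1))),
                                "S3", measure = "signed")
  expect_equal(unname(zt["s", ]), c(0, 0))
})

test_that("dominance percentages capture forced orderings, splits and ties", {
  tab <- make_table(list(s1 = c(A = 3, D = 1), s2 = c(A = 5, D = 2),
                         s3 = c(A = 2, D = 0.5)))
  d <- pairwise_dominance(tab, "S3")
  ad <- d[d$upper == "A" & d$left == "D", ]
  expect_equal(ad$pct_greater, 100)
  expect_equal(ad$pct_less, 0)
  expect_equal(ad$pct_equal, 0)

  # ties within tolerance
  tie <- make_table(list(s1 = c(A = 1, D = 1), s2 = c(A = 2, D = 2)))
  dt <- pairwise_dominance(tie, "S3")
  expect_equal(dt$pct_equal, c(100, 100))

  # antisymmetry and the 100% identity on a mixed table
  mix <- make_table(list(s1 = c(A = 3, D = 1), s2 = c(A = 1, D = 3),
                         s3 = c(A = 2, D = 2)))
  dm <- pairwise_dominance(mix, "S3")
  up <- dm[dm$upper == "A", ]; dn <- dm[dm$upper == "D", ]
  expect_equal(up$pct_greater, dn$pct_less)
  expect_equal(up$pct_less, dn$pct_greater)
  expect_equal(up$pct_greater + up$pct_less + up$pct_equal, 100)

  # magnitude comparison: a large negative sensitivity dominates
  mag <- make_table(list(s1 = c(A = 0.5, D = -2)))
  dmag <- pairwise_dominance(mag, "S3")
  expect_equal(dmag[dmag$upper == "D", "pct_greater"], 100)

  expect_error(pairwise_dominance(make_table(list(s = c(A = 1, D = 2))),
                                  "S3", label_filter = "nonexistent"),
               "relax the band")
})

test_that("log2 sensitivity ratios behave like signed magnitude ratios", {
  tab <- make_table(list(s1 = c(A = 2, D = -2), s2 = c(A = 4, D = -1)))
  r <- sensitivity_ratio(tab, c("A", "D"))
  expect_equal(sort(r$log2_ratio), c(0, 2))
  r_rev <- sensitivity_ratio(tab, c("D", "A"))
  expect_equal(sort(r_rev$log2_ratio), -sort(r$log2_ratio, decreasing = TRUE))

  zero <- make_table(list(s1 = c(A = 1, D = 0)))
  expect_warning(rz <- sensitivity_ratio(zero, c("A", "D")), "zero")
  expect_equal(nrow(rz), 0)
})

test_that("integral-sensitivity correlation detects exact and null relations", {
  mk <- function(f) {
    q <- seq(1, 50)
    df <- data.frame(set_id = paste0("s", seq_along(q)), label = "positive",
                     pattern = "S3", reaction = "A", q = q, s_log = f(q),
                     stringsAsFactors = FALSE)
    synthetic_sens_table(df)
  }
  expect_equal(integral_sensitivity_correlation(mk(function(q) 2 * q + 1))$r,
               1)
  expect_equal(integral_sensitivity_correlation(mk(function(q) -q))$r, -1)

  set.seed(12)
  noise <- mk(function(q) stats::rnorm(length(q)))
  noise$q <- stats::rnorm(nrow(noise))
  big <- do.call(rbind, replicate(20, as.data.frame(noise),
                                  simplify = FALSE))
  big$set_id <- paste0("s", seq_len(nrow(big)))
  big$q <- stats::rnorm(nrow(big))
  big$s_log <- stats::rnorm(nrow(big))
  r <- integral_sensitivity_correlation(synthetic_sens_table(big))$r
  expect_lt(abs(r), 0.1)

  const <- mk(function(q) rep(1, length(q)))
  expect_true(is.na(integral_sensitivity_correlation(const)$r))
})
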