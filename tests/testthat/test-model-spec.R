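# Model syntax parsing, parameter sets, implied moments, df counting.

test_that("parser counts free parameters and df correctly", {
  # just-identified one-factor, 3 items: marker fixes 1 loading,
  # q = 2 loadings + 3 residuals + 1 factor variance = 6, df = 0
  m3 <- parse_model("f1 =~ x1 + x2 + x3")
  expect_equal(m3$q, 6)
  expect_equal(m3$df, 0)

  # one-factor, 5 items, marker identification -> df = 5
  m5 <- one_factor_model(5)
  expect_equal(m5$df, 5)

  # two-factor 3+3 with free factor correlation -> df = 8
  m2f <- parse_model("pq =~ x1 + x2 + x3\nnq =~ x4 + x5 + x6")
  expect_equal(m2f$df, 8)
  expect_true(m2f$psi_free[1, 2])
})

test_that("parser handles fixed values, comments and identification modes", {
  m <- parse_model("f1 =~ x1 + 0.5*x2 + x3  # loading fixed\nf2 =~ x4 + x5\nf1 ~~ 0.7*f2")
  expect_false(m$lambda_free["x2", "f1"])
  expect_equal(m$lambda_value["x2", "f1"], 0.5)
  expect_false(m$psi_free[1, 2])
  expect_equal(m$psi_value[1, 2], 0.7)
  # f1's scale is set by the user-fixed loading, so its marker stays free;
  # f2 has no user-fixed loading, so its first item is fixed to 1
  expect_true(m$lambda_free["x1", "f1"])
  expect_equal(m$lambda_value["x4", "f2"], 1)
  expect_false(m$lambda_free["x4", "f2"])

  mu <- parse_model("f1 =~ x1 + x2 + x3", identification = "unit_factor_variance")
  expect_true(all(mu$lambda_free[, 1]))
  expect_false(mu$psi_free[1, 1])
  expect_equal(mu$psi_value[1, 1], 1)
  expect_equal(mu$df, 0)  # same df under both identifications
})

test_that("parser rejects malformed input with informative errors", {
  expect_error(parse_model("f1 =~ x1 + x2\ny ~ x1"), "reserved")
  expect_error(parse_model("f1 =~ x1 + x2\nf1 =~ x1"), "duplicate")
  expect_error(parse_model("f1 =~ x1 + x2\nx1 ~~ x2\nx1 ~~ x2"), "duplicate")
  expect_error(parse_model("f1 =~ x1 + x2\nx9 ~~ x1"), "unknown name")
  expect_error(parse_model("x1 ~~ x2"), "no factor")
  expect_error(parse_model("f1 =~ a*b*x1"), "syntax error")
  # t-rule: 2-item one-factor model with free residual covariance
  expect_error(parse_model("f1 =~ x1 + x2\nx1 ~~ x2"), "t-rule")
})

test_that("parse -> serialize -> parse round-trips the free/fixed pattern", {
  texts <- c(
    "f1 =~ x1 + x2 + x3 + x4 + x5",
    "pq =~ x1 + x2 + x3\nnq =~ x4 + x5 + x6\nx1 ~~ x2",
    "f1 =~ x1 + 0.5*x2 + x3\nf2 =~ x4 + x5\nf1 ~~ 0.25*f2\nx4 ~~ 0.1*x4")
  for (txt in texts) {
    m1 <- parse_model(txt)
    m2 <- parse_model(serialize_model(m1))
    expect_identical(m1$lambda_free, m2$lambda_free)
    expect_identical(m1$psi_free, m2$psi_free)
    expect_identical(m1$theta_free, m2$theta_free)
    expect_equal(m1$lambda_value, m2$lambda_value)
    expect_equal(m1$theta_value, m2$theta_value)
    expect_equal(m1$df, m2$df)
  }
})

test_that("implied covariance matches hand arithmetic", {
  # Lambda = [1,1]', Psi = [1], Theta = I2 -> [[2,1],[1,2]]
  ps <- parameter_set(matrix(c(1, 1), 2, 1), matrix(1), diag(2))
  expect_equal(unname(implied_covariance(ps)), matrix(c(2, 1, 1, 2), 2))

  # zero loadings -> Theta returned
  d <- diag(c(1.2, 0.7, 2))
  ps0 <- parameter_set(matrix(0, 3, 1), matrix(1), d)
  expect_equal(unname(implied_covariance(ps0)), d)

  # standardized one-factor, loadings .7: diagonal 1, off-diagonal .49
  ps5 <- parameter_set(matrix(0.7, 5, 1), matrix(1), diag(0.51, 5))
  sig <- implied_covariance(ps5)
  expect_equal(unname(diag(sig)), rep(1, 5))
  expect_equal(unname(sig[lower.tri(sig)]), rep(0.49, 10))
})

test_that("implied covariance is invariant to factor relabeling", {
  lam <- matrix(0, 6, 2); lam[1:3, 1] <- c(.6, .7, .65); lam[4:6, 2] <- c(.55, .7, .6)
  psi <- matrix(c(1, .3, .3, 1), 2)
  ps <- parameter_set(lam, psi, diag(0.5, 6))
  ps_swapped <- parameter_set(lam[, 2:1], psi[2:1, 2:1], diag(0.5, 6))
  expect_equal(unname(implied_covariance(ps)), unname(implied_covariance(ps_swapped)))
})

test_that("split_factor produces the two-factor misspecification", {
  pop <- one_factor_pop()
  # r = 1 collapses back to the one-factor implied covariance
  h1 <- split_factor(pop, list(c("x1", "x2"), c("x3", "x4", "x5")), r = 1)
  expect_equal(implied_covariance(h1), implied_covariance(pop), tolerance = 1e-12)

  # r = .70 scales cross-block covariances by .70, keeps within-block
  h70 <- split_factor(pop, list(c("x1", "x2"), c("x3", "x4", "x5")), r = 0.70)
  s0 <- implied_covariance(pop); s1 <- implied_covariance(h70)
  expect_equal(s1[1:2, 3:5], 0.70 * s0[1:2, 3:5], tolerance = 1e-12)
  expect_equal(s1[1:2, 1:2], s0[1:2, 1:2], tolerance = 1e-12)

  # r = 0 zeroes the cross-block covariances
  h0c <- split_factor(pop, list(1:2, 3:5), r = 0)
  expect_equal(unname(implied_covariance(h0c)[1:2, 3:5]), matrix(0, 2, 3))

  expect_error(split_factor(pop, list(1:2, 3:4), r = .7), "cover all items")
  expect_error(split_factor(pop, list(integer(0), 1:5), r = .7), "empty|cover")
  expect_error(split_factor(pop, list(1:2, 3:5), r = 1.5), "\\(-1, 1\\]")
})

test_that("add_residual_correlations sets theta[i,j] = r*sqrt(theta_ii theta_jj)", {
  pop <- one_factor_pop(rep(0.7, 4))
  # r = 0 is the identity
  same <- add_residual_correlations(pop, list(c("x1", "x2")), r = 0)
  expect_equal(implied_covariance(same), implied_covariance(pop), tolerance = 1e-12)

  # equal residual variances 0.5 -> covariance r * 0.5
  pop2 <- parameter_set(matrix(sqrt(0.5), 4, 1), matrix(1), diag(0.5, 4))
  h1 <- add_residual_correlations(pop2, list(c(1, 2)), r = 0.5)
  expect_equal(h1$theta[1, 2], 0.25)

  expect_error(add_residual_correlations(pop, list(c("x1", "x9")), 0.5), "unknown item")
  expect_error(add_residual_correlations(pop, list(c("x1", "x1")), 0.5), "distinct")
})

test_that("parameter_set validates symmetry, dimensions and definiteness", {
  expect_error(parameter_set(matrix(0.7, 3, 1), matrix(1), diag(2)), "dimension mismatch")
  bad_psi <- matrix(c(1, .5, .2, 1), 2)
  expect_error(parameter_set(matrix(0.5, 4, 2), bad_psi, diag(4)), "symmetric")
  # negative-definite implied covariance rejected
  expect_error(parameter_set(matrix(1, 2, 1), matrix(1), diag(-2, 2)),
               "positive definite")
})
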