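# Canned scenarios and the coefficient-transcription entry path.

test_that("all named scenarios build valid configurations; unknown names fail", {
  for (nm in c("example1_like", "example2_like", "null_contrast",
               "calibration_normal", "calibration_nonnormal")) {
    sc <- make_scenario(nm)
    expect_s3_class(sc, "named_scenario")
    expect_s3_class(sc$config, "study_config")
    expect_true(nzchar(sc$provenance))
  }
  expect_error(make_scenario("no_such_scenario"), "unknown scenario")
})

test_that("scenario populations encode the intended misspecifications", {
  sc1 <- make_scenario("example1_like")
  expect_equal(sc1$config$sim$n, 468L)
  h0 <- sc1$config$h0_population; h1 <- sc1$config$h1_populations[[1]]
  expect_equal(ncol(h0$lambda), 1)
  expect_equal(ncol(h1$lambda), 2)
  expect_equal(stats::cov2cor(h1$psi)[1, 2], 0.70)

  sc2 <- make_scenario("example2_like")
  expect_equal(sc2$config$sim$n, 474L)
  th <- sc2$config$h1_populations[[1]]$theta
  offdiag <- th[lower.tri(th)]
  expect_equal(sum(offdiag != 0), 2)  # exactly two residual covariances
  # each equals .50 * sqrt(theta_ii * theta_jj)
  idx <- which(lower.tri(th), arr.ind = TRUE)[offdiag != 0, , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    expect_equal(th[i, j], 0.5 * sqrt(th[i, i] * th[j, j]), tolerance = 1e-12)
  }

  expect_equal(make_scenario("null_contrast")$config$h1_populations[[1]],
               make_scenario("null_contrast")$config$h0_population)
})

test_that("scenario runs are reproducible under the pinned seed", {
  r1 <- run_scenario("example1_like", n_reps = 8, progress = FALSE)
  r2 <- run_scenario("example1_like", n_reps = 8, progress = FALSE)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$cutoffs, r2$cutoffs)
})

test_that("transcribe_paper_models assembles a config from supplied coefficients", {
  spec <- list(
    items = paste0("x", 1:6),
    loadings = list(pq = list(x1 = 0.62, x2 = 0.71, x3 = 0.58),
                    nq = list(x4 = 0.55, x5 = 0.68, x6 = 0.61)),
    residual_variances = list(x1 = 0.62, x2 = 0.50, x3 = 0.66,
                              x4 = 0.70, x5 = 0.54, x6 = 0.63),
    factor_covariance = 0.30,
    n = 474,
    h1 = list(type = "residual_correlations", r = 0.5,
              pairs = list(c("x1", "x2"), c("x4", "x6"))))
  cfg <- transcribe_paper_models(spec)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$analysis_model$df, 8)
  th <- cfg$h1_populations[[1]]$theta
  # two off-diagonal nonzeros with the r*sqrt(theta_ii theta_jj) values
  expect_equal(sum(th[lower.tri(th)] != 0), 2)
  expect_equal(th["x1", "x2"], 0.5 * sqrt(0.62 * 0.50), tolerance = 1e-12)

  # a missing loading is reported by item name
  bad <- spec; bad$loadings$nq$x6 <- NULL
  expect_error(transcribe_paper_models(bad), "x6")
  # split-type H1
  spec1 <- list(items = paste0("x", 1:5),
                loadings = list(f1 = as.list(setNames(c(.8, .7, .75, .6, .65),
                                                      paste0("x", 1:5)))),
                residual_variances = as.list(setNames(1 - c(.8, .7, .75, .6, .65)^2,
                                                      paste0("x", 1:5))),
                n = 468,
                h1 = list(type = "split", r = 0.7,
                          partition = list(c("x1", "x2"), c("x3", "x4", "x5"))))
  cfg1 <- transcribe_paper_models(spec1)
  expect_equal(ncol(cfg1$h1_populations[[1]]$lambda), 2)
})

test_that("the shipped YAML transcription example parses into a valid config", {
  skip_if_not_installed("yaml")
  path <- system.file("extdata", "example_transcription.yaml", package = "tailorcut")
  skip_if(path == "")
  cfg <- transcribe_paper_models(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$sim$n, 474L)
  expect_equal(cfg$estimator, "MLR")
  expect_equal(sum(cfg$h1_populations[[1]]$theta[lower.tri(diag(6))] != 0), 2)
})
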