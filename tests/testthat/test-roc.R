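# ROC curves, AUC, Youden cutoffs, screening.

test_that("AUC endpoints behave as the classical semantics require", {
  # fully separated, lower-better: AUC = 1
  d1 <- index_distributions(c(.01, .02), c(.05, .06), FALSE, "srmr")
  expect_equal(roc_curve(d1)$auc, 1)
  # identical samples: chance level
  d2 <- index_distributions(c(1, 2, 3), c(1, 2, 3), FALSE, "x")
  expect_equal(roc_curve(d2)$auc, 0.5)
  # interleaved: brute-force concordance 3/4
  d3 <- index_distributions(c(1, 3), c(2, 4), FALSE, "x")
  expect_equal(roc_curve(d3)$auc, 0.75)
  # reversed classes: AUC below .5 and flagged
  d4 <- index_distributions(c(.05, .06), c(.01, .02), FALSE, "x")
  expect_equal(roc_curve(d4)$auc, 0)
  expect_true(optimal_cutoff(d4)$flagged)
})

test_that("trapezoidal AUC equals pairwise concordance on random tied samples", {
  for (seed in 1:200) {
    d <- random_dist(seed, higher_is_better = seed %% 2 == 0)
    expect_equal(roc_curve(d)$auc, auc_pairwise(d), tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 17, 91)) {
    d <- random_dist(seed)
    r <- pROC::roc(response = c(rep(0, length(d$h0)), rep(1, length(d$h1))),
                   predictor = c(d$h0, d$h1), direction = "<", quiet = TRUE)
    expect_equal(roc_curve(d)$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals exhaustive search and its rates are self-consistent", {
  exhaustive_youden <- function(d) {
    cuts <- sort(unique(c(d$h0, d$h1)))
    best <- -Inf
    for (ct in cuts) {
      if (d$higher_is_better) { se <- mean(d$h1 < ct); sp <- mean(d$h0 >= ct) }
      else { se <- mean(d$h1 > ct); sp <- mean(d$h0 <= ct) }
      best <- max(best, se + sp - 1)
    }
    best
  }
  for (seed in 1:100) {
    d <- random_dist(seed, higher_is_better = seed %% 3 == 0)
    rep <- optimal_cutoff(d)
    expect_equal(rep$youden, exhaustive_youden(d), tolerance = 1e-12)
    # rates recomputed from confusion counts at the reported cutoff
    if (d$higher_is_better) {
      tp <- sum(d$h1 < rep$cutoff); tn <- sum(d$h0 >= rep$cutoff)
    } else {
      tp <- sum(d$h1 > rep$cutoff); tn <- sum(d$h0 <= rep$cutoff)
    }
    n1 <- length(d$h1); n0 <- length(d$h0)
    expect_equal(rep$sensitivity, tp / n1, tolerance = 1e-12)
    expect_equal(rep$specificity, tn / n0, tolerance = 1e-12)
    expect_equal(rep$accuracy, (tp + tn) / (n0 + n1), tolerance = 1e-12)
    expect_equal(rep$type1, 1 - rep$specificity, tolerance = 1e-12)
    expect_equal(rep$type2, 1 - rep$sensitivity, tolerance = 1e-12)
  }
})

test_that("spec toy case: h0 = {1,3}, h1 = {2,4} gives Youden 0.5", {
  d <- index_distributions(c(1, 3), c(2, 4), FALSE, "x")
  rep <- optimal_cutoff(d)
  expect_equal(rep$youden, 0.5)
  # cutoff 3 accepts {1,3} and flags {4}: the conservative optimum
  expect_equal(rep$cutoff, 3)
  expect_equal(rep$specificity, 1)
})

test_that("separated samples give a zero-error cutoff", {
  d <- index_distributions(rnorm(50, 0, .1), rnorm(50, 3, .1), FALSE, "chisq")
  rep <- optimal_cutoff(d)
  expect_equal(rep$type1, 0)
  expect_equal(rep$type2, 0)
  expect_equal(rep$accuracy, 1)
  # the reported cutoff is an observed value from the pooled sample
  expect_true(rep$cutoff %in% c(d$h0, d$h1))
})

test_that("monotone transforms preserve AUC and map the cutoff through", {
  for (seed in 1:25) {
    d <- random_dist(seed)
    tr <- function(x) exp(x / 2) + x   # strictly increasing
    d_tr <- index_distributions(tr(d$h0), tr(d$h1), d$higher_is_better, "tr")
    expect_equal(roc_curve(d_tr)$auc, roc_curve(d)$auc, tolerance = 1e-12)
    r1 <- optimal_cutoff(d); r2 <- optimal_cutoff(d_tr)
    expect_equal(r2$cutoff, tr(r1$cutoff), tolerance = 1e-9)
    expect_equal(r2$youden, r1$youden, tolerance = 1e-12)
  }
})

test_that("screening keeps, ranks and discards indices by AUC", {
  mk <- function(name, auc_target) {
    # build a distribution with roughly the requested separability
    set.seed(match(name, c("chisq", "cfi", "rmsea", "srmr")))
    shift <- qnorm(auc_target) * sqrt(2)
    optimal_cutoff(index_distributions(rnorm(200), rnorm(200, shift), FALSE, name))
  }
  reports <- list(mk("chisq", .9), mk("cfi", .6), mk("rmsea", .85), mk("srmr", .97))
  sc <- screen_indices(reports, auc_threshold = 0.80)
  expect_setequal(names(sc$kept), c("chisq", "rmsea", "srmr"))
  expect_equal(names(sc$discarded), "cfi")
  expect_equal(sc$discarded$cfi$reason, "AUC below threshold")
  expect_equal(sc$best_index, "srmr")

  # exact ties are all flagged co-best
  r1 <- optimal_cutoff(index_distributions(c(1, 2), c(3, 4), FALSE, "a"))
  r2 <- optimal_cutoff(index_distributions(c(1, 2), c(3, 4), FALSE, "b"))
  sc2 <- screen_indices(list(r1, r2), 0.80)
  expect_setequal(sc2$best_index, c("a", "b"))

  # threshold above 1: everything discarded, warning path
  expect_warning(sc3 <- screen_indices(reports, auc_threshold = 1.01),
                 "not be strong enough")
  expect_length(sc3$kept, 0)
  expect_length(sc3$best_index, 0)
})

test_that("boundary values count as passing the cutoff", {
  r_low <- optimal_cutoff(index_distributions(c(1, 2), c(5, 6), FALSE, "x"))
  expect_true(passes_cutoff(r_low, r_low$cutoff))
  expect_false(passes_cutoff(r_low, r_low$cutoff + 1e-9))
  r_high <- optimal_cutoff(index_distributions(c(.98, .99), c(.90, .91), TRUE, "cfi"))
  expect_true(passes_cutoff(r_high, r_high$cutoff))
  expect_false(passes_cutoff(r_high, r_high$cutoff - 1e-9))
})
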