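# Shared fixtures: all built in code, deterministic under fixed seeds.

# standardized one-factor population: unit item variances, theta = 1 - lambda^2
one_factor_pop <- function(loadings = c(0.8, 0.7, 0.75, 0.6, 0.65)) {
  parameter_set(lambda = matrix(loadings, ncol = 1),
                psi = matrix(1, 1, 1),
                theta = diag(1 - loadings^2),
                item_names = paste0("x", seq_along(loadings)))
}

one_factor_model <- function(p = 5, ...) {
  parse_model(paste("f1 =~", paste(paste0("x", 1:p), collapse = " + ")), ...)
}

# random PD covariance matrix (factor structure plus diagonal noise)
random_cov <- function(p, seed) {
  set.seed(seed)
  L <- matrix(rnorm(p * 2, sd = 0.6), p, 2)
  S <- tcrossprod(L) + diag(runif(p, 0.3, 1.2))
  (S + t(S)) / 2
}

# random H0/H1 value samples with deliberate ties (rounded to 1 decimal)
random_dist <- function(seed, higher_is_better = FALSE) {
  set.seed(seed)
  n0 <- sample(3:50, 1); n1 <- sample(3:50, 1)
  shift <- runif(1, -0.5, 1.5)
  h0 <- round(rnorm(n0), 1)
  h1 <- round(rnorm(n1, mean = if (higher_is_better) -shift else shift), 1)
  index_distributions(h0, h1, higher_is_better, "test_index")
}

# independent F_ML implementation used as an optimizer-agnostic oracle:
# same discrepancy, written from scratch, minimized without analytic gradients
oracle_fml_min <- function(model, S) {
  map <- tailorcut:::param_map(model)
  fml <- function(x) {
    pr <- tailorcut:::unpack_params(model, map, x)
    sigma <- pr$lambda %*% pr$psi %*% t(pr$lambda) + pr$theta
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(1e10)
    log(det(sigma)) - log(det(S)) + sum(diag(S %*% solve(sigma))) - nrow(S)
  }
  x0 <- tailorcut:::start_values(model, map, S)
  o <- optim(x0, fml, method = "BFGS", control = list(maxit = 2000, reltol = 1e-15))
  o2 <- optim(o$par, fml, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-15))
  min(o$value, o2$value)
}

skewness_of <- function(x) mean((x - mean(x))^3) / sd(x)^3
exkurt_of <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
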