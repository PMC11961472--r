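#' Fleishman power-transform coefficients for target skewness and kurtosis
#'
#' Solves for coefficients (a, b, c, d) of the cubic transform
#' \eqn{Y = a + bZ + cZ^2 + dZ^3}, \eqn{Z \sim N(0,1)}, such that Y has mean
#' 0, variance 1 and the requested marginal skewness and excess kurtosis;
#' \eqn{a = -c} enforces the zero mean. The three moment equations are solved
#' by Newton iteration from the normal solution (b, c, d) = (1, 0, 0).
#'
#' @param skew Target skewness.
#' @param exkurt Target excess kurtosis; must satisfy the feasibility bound
#'   \code{exkurt >= skew^2 - 2}.
#' @param tol Convergence tolerance on the moment equations.
#' @return Named numeric vector \code{c(a, b, c, d)}.
#' @examples
#' fleishman_coefficients(0, 0)  # identity: (0, 1, 0, 0)
#' @export
fleishman_coefficients <- function(skew, exkurt, tol = 1e-10) {
  stopifnot(is.numeric(skew), is.numeric(exkurt), length(skew) == 1L, length(exkurt) == 1L)
  if (exkurt < skew^2 - 2)
    stop("infeasible margin: excess kurtosis ", exkurt,
         " violates the bound skew^2 - 2 = ", skew^2 - 2)
  if (skew == 0 && exkurt == 0)
    return(c(a = 0, b = 1, c = 0, d = 0))

  moments <- function(x) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    b2 <- b * b; c2 <- cc * cc; d2 <- d * d; bd <- b * d
    c(b2 + 6 * bd + 2 * c2 + 15 * d2 - 1,
      2 * cc * (b2 + 24 * bd + 105 * d2 + 2) - skew,
      24 * (bd + c2 * (1 + b2 + 28 * bd) +
              d2 * (12 + 48 * bd + 141 * c2 + 225 * d2)) - exkurt)
  }
  jac <- function(x) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    matrix(c(
      2 * b + 6 * d,                         4 * cc,                         6 * b + 30 * d,
      2 * cc * (2 * b + 24 * d),             2 * (b^2 + 24 * b * d + 105 * d^2 + 2), 2 * cc * (24 * b + 210 * d),
      24 * (d + cc^2 * (2 * b + 28 * d) + 48 * d^3),
      24 * (2 * cc * (1 + b^2 + 28 * b * d) + 282 * d^2 * cc),
      24 * (b + 28 * b * cc^2 + 2 * d * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2) +
              d^2 * (48 * b + 900 * d))
    ), 3, 3, byrow = TRUE)
  }

  starts <- list(c(1, 0, 0),
                 c(0.9, 0.1 * sign(skew + 1e-12), 0.05),
                 c(0.8, 0.2 * sign(skew + 1e-12), 0.1))
  for (x0 in starts) {
    x <- x0
    ok <- FALSE
    for (it in 1:200) {
      g <- moments(x)
      if (max(abs(g)) < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac(x), g), error = function(e) NULL)
      if (is.null(step)) break
      # damped Newton: halve until the residual decreases
      lam <- 1
      repeat {
        xn <- x - lam * step
        if (max(abs(moments(xn))) < max(abs(g)) || lam < 1e-8) break
        lam <- lam / 2
      }
      x <- xn
    }
    if (ok) return(c(a = -x[2], b = x[1], c = x[2], d = x[3]))
  }
  stop("Fleishman coefficient solve did not converge for skew = ", skew,
       ", excess kurtosis = ", exkurt)
}

#' Intermediate correlation for the Vale-Maurelli construction
#'
#' Given the Fleishman coefficients of two margins, finds the correlation
#' \eqn{\rho} to impose on the underlying standard normals so that the
#' transformed variables attain the target correlation. \eqn{\rho} solves
#' the cubic
#' \eqn{r = \rho(b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j) +
#'       \rho^2 (2 c_i c_j) + \rho^3 (6 d_i d_j)}.
#'
#' @param r_target Target product-moment correlation of the transformed pair.
#' @param coef_i,coef_j Coefficient vectors from [fleishman_coefficients()].
#' @return The intermediate correlation, a number in \eqn{[-1, 1]}.
#' @export
intermediate_correlation <- function(r_target, coef_i, coef_j) {
  if (abs(r_target) > 1) stop("target correlation must lie in [-1, 1]")
  if (r_target == 0) return(0)
  bi <- coef_i[["b"]]; ci <- coef_i[["c"]]; di <- coef_i[["d"]]
  bj <- coef_j[["b"]]; cj <- coef_j[["c"]]; dj <- coef_j[["d"]]
  k1 <- bi * bj + 3 * bi * dj + 3 * di * bj + 9 * di * dj
  k2 <- 2 * ci * cj
  k3 <- 6 * di * dj
  # k3 rho^3 + k2 rho^2 + k1 rho - r = 0
  roots <- polyroot(c(-r_target, k1, k2, k3))
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[real >= -1 - 1e-10 & real <= 1 + 1e-10]
  if (!length(real))
    stop("no real intermediate correlation in [-1, 1] for target ", r_target)
  rho <- real[which.min(abs(real - r_target))]
  min(1, max(-1, rho))
}

#' Simulation configuration
#'
#' @param n Sample size per replicate dataset.
#' @param n_reps Number of replicate datasets per population model.
#' @param master_seed Integer master seed; every replicate stream is derived
#'   from it deterministically.
#' @param margins \code{"normal"}, or a data frame / list with numeric
#'   elements \code{skewness} and \code{excess_kurtosis}, one value per item
#'   (length-1 values are recycled).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n, n_reps = 500, master_seed = 1, margins = "normal") {
  stopifnot(n >= 2, n_reps >= 1)
  master_seed <- as.integer(master_seed)
  if (!identical(margins, "normal")) {
    if (!all(c("skewness", "excess_kurtosis") %in% names(margins)))
      stop("margins must be \"normal\" or have elements 'skewness' and 'excess_kurtosis'")
    bad <- margins$excess_kurtosis < margins$skewness^2 - 2
    if (any(bad))
      stop("infeasible margins for item(s) ", paste(which(bad), collapse = ", "),
           ": excess kurtosis below skew^2 - 2")
  }
  structure(list(n = as.integer(n), n_reps = as.integer(n_reps),
                 master_seed = master_seed, margins = margins),
            class = "sim_config")
}

# Deterministic per-replicate substream seed from (master_seed, label, rep).
# Simple multiplicative mixing kept below 2^31; order-independent across reps.
replicate_seed <- function(master_seed, label, rep_index) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 1000000007
  s <- (as.double(master_seed) %% 2147483647) * 2654435761 + h * 97 + as.double(rep_index)
  as.integer(s %% 2147483563) + 1L
}

# Precompute everything rep-independent for Vale-Maurelli generation:
# per-item Fleishman coefficients, the intermediate correlation matrix and
# its Cholesky factor, and the item standard deviations.
vm_setup <- function(pop, margins) {
  sigma <- implied_covariance(pop)
  p <- nrow(sigma)
  sds <- sqrt(diag(sigma))
  R <- stats::cov2cor(sigma)
  if (identical(margins, "normal")) {
    coefs <- rep(list(c(a = 0, b = 1, c = 0, d = 0)), p)
  } else {
    sk <- rep_len(margins$skewness, p)
    ku <- rep_len(margins$excess_kurtosis, p)
    coefs <- lapply(seq_len(p), function(i) fleishman_coefficients(sk[i], ku[i]))
  }
  Rint <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    Rint[i, j] <- Rint[j, i] <-
      intermediate_correlation(R[i, j], coefs[[i]], coefs[[j]])
  }
  ch <- tryCatch(chol(Rint), error = function(e) NULL)
  if (is.null(ch)) {
    adj <- abs(Rint - R); diag(adj) <- 0
    worst <- which(adj == max(adj), arr.ind = TRUE)[1, ]
    stop("intermediate correlation matrix is not positive definite after the ",
         "Vale-Maurelli adjustment; largest adjustment at item pair (",
         pop$item_names[worst[1]], ", ", pop$item_names[worst[2]], ")")
  }
  list(chol = ch, coefs = coefs, sds = sds, p = p, items = pop$item_names)
}

vm_draw <- function(setup, n, seed) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * setup$p), n, setup$p) %*% setup$chol
  Y <- Z
  for (i in seq_len(setup$p)) {
    cf <- setup$coefs[[i]]
    if (cf[["c"]] != 0 || cf[["d"]] != 0 || cf[["b"]] != 1) {
      z <- Z[, i]
      Y[, i] <- cf[["a"]] + cf[["b"]] * z + cf[["c"]] * z^2 + cf[["d"]] * z^3
    }
  }
  Y <- sweep(Y, 2, setup$sds, `*`)
  colnames(Y) <- setup$items
  Y
}

#' Generate one replicate dataset from a population model
#'
#' Draws an n x p sample whose population covariance is the implied
#' covariance of \code{pop}. Margins are normal or non-normal via the
#' Fleishman/Vale-Maurelli construction; with normal margins the transform
#' is the identity, so the non-normal code path reproduces the plain normal
#' draw exactly. Deterministic given \code{(master_seed, label, rep_index)}.
#'
#' @param pop A \code{cfa_params} population model.
#' @param cfg A [sim_config()].
#' @param rep_index Replicate number (1-based).
#' @param label Population label entering the seed derivation (default
#'   \code{"pop"}; the pipeline uses \code{"H0"}, \code{"H1"}, ...).
#' @return An \code{n x p} numeric matrix with item columns.
#' @export
generate_dataset <- function(pop, cfg, rep_index, label = "pop") {
  stopifnot(inherits(pop, "cfa_params"), inherits(cfg, "sim_config"), rep_index >= 1)
  setup <- vm_setup(pop, cfg$margins)
  vm_draw(setup, cfg$n, replicate_seed(cfg$master_seed, label, rep_index))
}

#' Estimate marginal skewness and excess kurtosis of a dataset
#'
#' Moment-based estimates (biased, consistent), per item. Used to match a
#' simulation's response distribution to an empirical dataset.
#'
#' @param data Numeric matrix or data frame, rows = respondents.
#' @return Data frame with columns \code{skewness} and
#'   \code{excess_kurtosis}, one row per item.
#' @export
estimate_margins <- function(data) {
  x <- as.matrix(data)
  ctr <- scale(x, center = TRUE, scale = FALSE)
  m2 <- colMeans(ctr^2)
  data.frame(skewness = colMeans(ctr^3) / m2^1.5,
             excess_kurtosis = colMeans(ctr^4) / m2^2 - 3,
             row.names = colnames(x))
}
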