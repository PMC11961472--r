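# Maximum-likelihood covariance-structure estimation for CFA models.
#
# The discrepancy minimized is the normal-theory ML fit function
#   F_ML(theta) = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^-1) - p
# over the free parameters of (lambda, psi, theta). The test statistic uses
# the normal-likelihood multiplier T = n * F_min by default (an (n-1)
# Wishart multiplier is available behind `multiplier`).

# ---- free-parameter packing -------------------------------------------------

# index tables mapping the free-parameter vector to matrix cells
param_map <- function(model) {
  lam <- which(model$lambda_free)                       # column-major linear idx
  psi_low <- which(lower.tri(model$psi_free, diag = TRUE) & model$psi_free)
  th_low <- which(lower.tri(model$theta_free, diag = TRUE) & model$theta_free)
  m <- length(model$factors); p <- model$p
  list(lam = lam,
       psi = psi_low, psi_rc = arrayInd(psi_low, c(m, m)),
       theta = th_low, theta_rc = arrayInd(th_low, c(p, p)),
       n_lam = length(lam), n_psi = length(psi_low), n_theta = length(th_low))
}

unpack_params <- function(model, map, x) {
  lambda <- model$lambda_value
  psi <- model$psi_value
  theta <- model$theta_value
  i <- 0L
  if (map$n_lam) { lambda[map$lam] <- x[seq_len(map$n_lam)]; i <- map$n_lam }
  if (map$n_psi) {
    v <- x[i + seq_len(map$n_psi)]; i <- i + map$n_psi
    for (k in seq_len(map$n_psi)) {
      r <- map$psi_rc[k, 1]; cc <- map$psi_rc[k, 2]
      psi[r, cc] <- psi[cc, r] <- v[k]
    }
  }
  if (map$n_theta) {
    v <- x[i + seq_len(map$n_theta)]
    for (k in seq_len(map$n_theta)) {
      r <- map$theta_rc[k, 1]; cc <- map$theta_rc[k, 2]
      theta[r, cc] <- theta[cc, r] <- v[k]
    }
  }
  list(lambda = lambda, psi = psi, theta = theta)
}

start_values <- function(model, map, S) {
  sds <- sqrt(diag(S))
  x <- numeric(map$n_lam + map$n_psi + map$n_theta)
  if (map$n_lam) {
    rc <- arrayInd(map$lam, c(model$p, length(model$factors)))
    x[seq_len(map$n_lam)] <- 0.7 * sds[rc[, 1]]
  }
  i <- map$n_lam
  if (map$n_psi) {
    v0 <- 0.5 * mean(diag(S))
    for (k in seq_len(map$n_psi)) {
      x[i + k] <- if (map$psi_rc[k, 1] == map$psi_rc[k, 2]) v0 else 0.3 * v0
    }
    # marker identification: implied variance of the marker item is psi + theta,
    # so a factor-variance start near half the marker variance works well
    i <- i + map$n_psi
  }
  if (map$n_theta) {
    for (k in seq_len(map$n_theta)) {
      r <- map$theta_rc[k, 1]; cc <- map$theta_rc[k, 2]
      x[i + k] <- if (r == cc) 0.5 * S[r, r] else 0
    }
  }
  x
}

# F_ML and its analytic gradient. Non-PD Sigma yields a large finite value.
ml_objective <- function(model, map, S, logdetS) {
  p <- model$p
  fn <- function(x) {
    pr <- unpack_params(model, map, x)
    sigma <- pr$lambda %*% pr$psi %*% t(pr$lambda) + pr$theta
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    val <- logdet - logdetS + sum(S * inv) - p
    if (!is.finite(val)) 1e10 else val
  }
  gr <- function(x) {
    pr <- unpack_params(model, map, x)
    sigma <- pr$lambda %*% pr$psi %*% t(pr$lambda) + pr$theta
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(numeric(length(x)))
    inv <- chol2inv(ch)
    A <- inv - inv %*% S %*% inv       # dF/dSigma up to symmetry handling
    g <- numeric(length(x))
    if (map$n_lam) {
      Glam <- 2 * A %*% pr$lambda %*% pr$psi
      g[seq_len(map$n_lam)] <- Glam[map$lam]
    }
    i <- map$n_lam
    if (map$n_psi) {
      Gpsi <- t(pr$lambda) %*% A %*% pr$lambda
      for (k in seq_len(map$n_psi)) {
        r <- map$psi_rc[k, 1]; cc <- map$psi_rc[k, 2]
        g[i + k] <- if (r == cc) Gpsi[r, r] else 2 * Gpsi[r, cc]
      }
      i <- i + map$n_psi
    }
    if (map$n_theta) {
      for (k in seq_len(map$n_theta)) {
        r <- map$theta_rc[k, 1]; cc <- map$theta_rc[k, 2]
        g[i + k] <- if (r == cc) A[r, r] else 2 * A[r, cc]
      }
    }
    g
  }
  list(fn = fn, gr = gr)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a CFA model to a sample covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML} = \log|\Sigma(\theta)| - \log|S| + tr(S\Sigma(\theta)^{-1}) - p}
#' over the model's free parameters by quasi-Newton (BFGS) iteration with an
#' analytic gradient, restarting once from perturbed start values on failure.
#' Improper (Heywood) solutions are retained and flagged, not raised.
#'
#' @param model A \code{cfa_model} from [parse_model()].
#' @param S Sample covariance matrix (symmetric, positive definite).
#' @param n Sample size used for the test-statistic multiplier.
#' @param multiplier \code{"n"} (default, normal-likelihood convention,
#'   \eqn{T = n F_{min}}) or \code{"n-1"} (Wishart).
#' @param max_iter,grad_tol Optimizer limits: iteration cap and the
#'   max-norm gradient threshold declaring convergence.
#' @return An object of class \code{cfa_fit}: parameter estimates
#'   (\code{params}), \code{F_min}, test statistic \code{T_stat}, \code{df},
#'   scaling factor \code{c} (1 for plain ML), \code{T_scaled},
#'   \code{converged} and \code{proper} flags, baseline-model statistics,
#'   the implied covariance \code{Sigma_hat}, and \code{S}, \code{n}.
#' @export
fit_ml <- function(model, S, n, multiplier = c("n", "n-1"),
                   max_iter = 500L, grad_tol = 1e-6) {
  multiplier <- match.arg(multiplier)
  stopifnot(inherits(model, "cfa_model"))
  S <- as.matrix(S)
  p <- model$p
  if (nrow(S) != p || ncol(S) != p)
    stop("S must be ", p, " x ", p, " to match the model")
  if (!is.null(colnames(S)) && !all(model$items %in% colnames(S))) {
    # unnamed or mismatched columns: assume spec order
  } else if (!is.null(colnames(S))) {
    S <- S[model$items, model$items]
  }
  S <- (S + t(S)) / 2
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) stop("sample covariance matrix S is singular or not positive definite")
  logdetS <- 2 * sum(log(diag(chS)))

  map <- param_map(model)
  obj <- ml_objective(model, map, S, logdetS)
  x0 <- start_values(model, map, S)

  run_opt <- function(x_start) {
    stats::optim(x_start, obj$fn, obj$gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-14))
  }
  opt <- run_opt(x0)
  gnorm <- max(abs(obj$gr(opt$par)))
  if (gnorm > grad_tol) {
    # deterministic perturbed restart
    opt2 <- run_opt(x0 * 1.25 + 0.01)
    if (obj$fn(opt2$par) < obj$fn(opt$par)) opt <- opt2
    gnorm <- max(abs(obj$gr(opt$par)))
  }
  converged <- is.finite(opt$value) && opt$value < 1e9 && gnorm <= grad_tol * 10
  # df = 0 models legitimately sit at F = 0 where curvature can stall BFGS
  if (!converged && model$df == 0 && opt$value < 1e-8) converged <- TRUE

  pr <- unpack_params(model, map, opt$par)
  est <- parameter_set(pr$lambda, pr$psi, pr$theta, model$items, model$factors,
                       check_pd = FALSE)
  sigma_hat <- implied_covariance(est)
  F_min <- max(0, obj$fn(opt$par))
  mult <- if (multiplier == "n") n else n - 1
  T_stat <- mult * F_min

  psi_d <- diag(as.matrix(est$psi)); theta_d <- diag(est$theta)
  corr_ok <- TRUE
  if (length(psi_d) > 1 && all(psi_d > 0)) {
    pc <- stats::cov2cor(est$psi)
    corr_ok <- max(abs(pc[lower.tri(pc)])) <= 1 + 1e-8
  }
  proper <- all(theta_d >= -1e-8) && all(psi_d >= -1e-8) && corr_ok

  base <- fit_baseline(S, n, multiplier = multiplier)

  structure(list(model = model, params = est, F_min = F_min, T_stat = T_stat,
                 df = model$df, n = n, multiplier = multiplier,
                 c = 1, T_scaled = T_stat,
                 converged = converged, proper = proper,
                 baseline_T = base$baseline_T, baseline_df = base$baseline_df,
                 baseline_c = 1, baseline_F = base$baseline_F,
                 S = S, Sigma_hat = sigma_hat,
                 estimator = "ML", grad_norm = gnorm,
                 free_par = opt$par, param_map = map),
            class = "cfa_fit")
}

#' Independence-baseline model fit (closed form)
#'
#' The baseline model frees only the item variances and fixes all
#' covariances to zero; its ML solution is \code{diag(S)}, so
#' \eqn{F_b = \log|diag(S)| - \log|S|} in closed form, with
#' \eqn{df_b = p(p-1)/2}.
#'
#' @inheritParams fit_ml
#' @return List with \code{baseline_T}, \code{baseline_df},
#'   \code{baseline_F}.
#' @export
fit_baseline <- function(S, n, multiplier = c("n", "n-1")) {
  multiplier <- match.arg(multiplier)
  S <- as.matrix(S); S <- (S + t(S)) / 2
  p <- nrow(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("sample covariance matrix S is singular or not positive definite")
  F_b <- sum(log(diag(S))) - 2 * sum(log(diag(ch)))
  F_b <- max(0, F_b)
  mult <- if (multiplier == "n") n else n - 1
  list(baseline_T = mult * F_b, baseline_df = p * (p - 1) / 2, baseline_F = F_b)
}

# ---- robust (mean-scaled) correction ---------------------------------------

# duplication matrix mapping vech to vec, p^2 x p(p+1)/2
duplication_matrix <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  k <- 0L
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1L
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

# normal-theory weight matrix V = 0.5 D' (Sigma^-1 x Sigma^-1) D at Sigma
normal_weight <- function(sigma_inv, D) {
  0.5 * t(D) %*% (sigma_inv %x% sigma_inv) %*% D
}

# Delta = d vech(Sigma)/d theta at the estimate, one column per free parameter
model_delta <- function(model, map, params) {
  p <- model$p
  lambda <- params$lambda; psi <- params$psi
  cols <- list()
  if (map$n_lam) {
    rc <- arrayInd(map$lam, c(p, length(model$factors)))
    LP <- lambda %*% psi
    for (k in seq_len(map$n_lam)) {
      i <- rc[k, 1]; j <- rc[k, 2]
      dS <- matrix(0, p, p)
      dS[i, ] <- dS[i, ] + LP[, j]
      dS[, i] <- dS[, i] + LP[, j]
      cols[[length(cols) + 1L]] <- vech(dS)
    }
  }
  if (map$n_psi) {
    for (k in seq_len(map$n_psi)) {
      r <- map$psi_rc[k, 1]; cc <- map$psi_rc[k, 2]
      E <- matrix(0, length(model$factors), length(model$factors))
      E[r, cc] <- E[cc, r] <- 1
      cols[[length(cols) + 1L]] <- vech(lambda %*% E %*% t(lambda))
    }
  }
  if (map$n_theta) {
    for (k in seq_len(map$n_theta)) {
      r <- map$theta_rc[k, 1]; cc <- map$theta_rc[k, 2]
      dS <- matrix(0, p, p)
      dS[r, cc] <- dS[cc, r] <- 1
      cols[[length(cols) + 1L]] <- vech(dS)
    }
  }
  do.call(cbind, cols)
}

# empirical ADF fourth-moment covariance matrix of vech(S), divisor n
adf_gamma <- function(data) {
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  z <- scale(x, center = TRUE, scale = FALSE)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  W <- z[, idx[, 1], drop = FALSE] * z[, idx[, 2], drop = FALSE]
  Wc <- scale(W, center = TRUE, scale = FALSE)
  crossprod(Wc) / n
}

#' Satorra-Bentler-type mean-scaling correction
#'
#' Computes the scaling factor \eqn{c = tr(U\hat\Gamma)/df}, where
#' \eqn{\hat\Gamma} is the empirical (asymptotically distribution-free)
#' fourth-moment covariance matrix of vech(S) and
#' \eqn{U = V - V\Delta(\Delta'V\Delta)^{-1}\Delta'V} is the normal-theory
#' residual weight projection at the estimate. The scaled statistic
#' \eqn{T/c} restores the mean calibration of the chi-square statistic under
#' non-normal data; it is the mean-scaled robust statistic reported by MLR
#' estimation. The baseline model's factor is computed analogously.
#'
#' @param data The raw n x p data matrix the fit was based on.
#' @param model The \code{cfa_model} that was fitted.
#' @param fit The [fit_ml()] result to correct.
#' @return The input \code{cfa_fit} with \code{c}, \code{T_scaled},
#'   \code{baseline_c} filled in and \code{estimator = "MLR"}.
#' @export
robust_correction <- function(data, model, fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$converged) stop("robust correction requires a converged fit")
  if (model$df == 0) {
    # saturated: no misfit to scale
    fit$c <- NA_real_
    fit$T_scaled <- fit$T_stat
    return(fit)
  }
  x <- as.matrix(data)
  if (!is.null(colnames(x)) && all(model$items %in% colnames(x)))
    x <- x[, model$items, drop = FALSE]
  p <- model$p
  ps <- p * (p + 1) / 2
  if (nrow(x) <= ps)
    warning("sample size ", nrow(x), " does not exceed the ", ps,
            " distinct second-order moments; the ADF fourth-moment matrix is rank-deficient")
  Gamma <- adf_gamma(x)
  D <- duplication_matrix(p)

  scale_factor <- function(sigma, delta, df) {
    sigma_inv <- solve(sigma)
    V <- normal_weight(sigma_inv, D)
    VD <- V %*% delta
    B <- tryCatch(solve(t(delta) %*% VD, t(VD)), error = function(e) NULL)
    if (is.null(B)) return(NA_real_)
    U <- V - VD %*% B
    sum(diag(U %*% Gamma)) / df
  }

  delta <- model_delta(model, fit$param_map, fit$params)
  c_hat <- scale_factor(fit$Sigma_hat, delta, fit$df)
  if (!is.finite(c_hat) || c_hat <= 0) {
    warning("fourth-moment matrix led to a degenerate scaling factor; falling back to c = 1")
    c_hat <- 1
    fit$scaling_fallback <- TRUE
  }
  fit$c <- c_hat
  fit$T_scaled <- fit$T_stat / c_hat

  # baseline: free parameters are the p variances, Delta columns vech(E_ii)
  delta_b <- matrix(0, ps, p)
  dpos <- match(paste(seq_len(p), seq_len(p)),
                apply(which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE), 1,
                      function(rc) paste(rc[1], rc[2])))
  for (i in seq_len(p)) delta_b[dpos[i], i] <- 1
  c_b <- scale_factor(diag(diag(fit$S)), delta_b, fit$baseline_df)
  if (!is.finite(c_b) || c_b <= 0) c_b <- 1
  fit$baseline_c <- c_b
  fit$estimator <- "MLR"
  fit
}

#' Fit a CFA model to raw data
#'
#' Convenience wrapper: centers the data, forms the sample covariance with
#' divisor matching the test-statistic multiplier, calls [fit_ml()] and,
#' for \code{estimator = "MLR"}, applies [robust_correction()].
#'
#' @param model A \code{cfa_model}.
#' @param data n x p matrix or data frame of item responses.
#' @param estimator \code{"ML"} or \code{"MLR"}.
#' @inheritParams fit_ml
#' @return A \code{cfa_fit}.
#' @export
fit_cfa <- function(model, data, estimator = c("ML", "MLR"),
                    multiplier = c("n", "n-1")) {
  estimator <- match.arg(estimator)
  multiplier <- match.arg(multiplier)
  x <- as.matrix(data)
  if (!is.null(colnames(x)) && all(model$items %in% colnames(x)))
    x <- x[, model$items, drop = FALSE]
  n <- nrow(x)
  z <- scale(x, center = TRUE, scale = FALSE)
  S <- crossprod(z) / if (multiplier == "n") n else n - 1
  fit <- fit_ml(model, S, n, multiplier = multiplier)
  if (estimator == "MLR" && fit$converged) fit <- robust_correction(x, model, fit)
  fit
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("CFA fit (", x$estimator, "): T = ", format(x$T_stat, digits = 5),
      ", df = ", x$df, sep = "")
  if (x$estimator == "MLR")
    cat(", scaled T = ", format(x$T_scaled, digits = 5),
        " (c = ", format(x$c, digits = 4), ")", sep = "")
  cat("\n  converged:", x$converged, " proper:", x$proper, "\n")
  invisible(x)
}
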