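#' Construct a CFA parameter set (population model or fitted solution)
#'
#' A parameter set fully determines a covariance structure
#' \eqn{\Sigma = \Lambda \Psi \Lambda' + \Theta}: loadings \code{lambda}
#' (p x m), factor covariance \code{psi} (m x m) and residual covariance
#' \code{theta} (p x p).
#'
#' @param lambda Numeric p x m loading matrix.
#' @param psi Numeric m x m symmetric factor covariance matrix.
#' @param theta Numeric p x p symmetric residual covariance matrix.
#' @param item_names,factor_names Optional labels; taken from dimnames when
#'   missing.
#' @param check_pd Require the implied covariance to be positive definite
#'   (default \code{TRUE}; a valid population model must be).
#' @return An object of class \code{cfa_params}.
#' @examples
#' pop <- parameter_set(lambda = matrix(0.7, 5, 1), psi = matrix(1, 1, 1),
#'                      theta = diag(0.51, 5))
#' implied_covariance(pop)[1, 2]  # 0.49
#' @export
parameter_set <- function(lambda, psi, theta, item_names = NULL,
                          factor_names = NULL, check_pd = TRUE) {
  lambda <- as.matrix(lambda); psi <- as.matrix(psi); theta <- as.matrix(theta)
  p <- nrow(lambda); m <- ncol(lambda)
  if (nrow(psi) != m || ncol(psi) != m)
    stop("dimension mismatch: psi must be ", m, " x ", m, " to match lambda")
  if (nrow(theta) != p || ncol(theta) != p)
    stop("dimension mismatch: theta must be ", p, " x ", p, " to match lambda")
  if (max(abs(psi - t(psi))) > 1e-10) stop("psi is not symmetric")
  if (max(abs(theta - t(theta))) > 1e-10) stop("theta is not symmetric")
  psi <- (psi + t(psi)) / 2
  theta <- (theta + t(theta)) / 2
  if (is.null(item_names)) item_names <- rownames(lambda)
  if (is.null(item_names)) item_names <- paste0("x", seq_len(p))
  if (is.null(factor_names)) factor_names <- colnames(lambda)
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(m))
  dimnames(lambda) <- list(item_names, factor_names)
  dimnames(psi) <- list(factor_names, factor_names)
  dimnames(theta) <- list(item_names, item_names)
  out <- structure(list(lambda = lambda, psi = psi, theta = theta,
                        item_names = item_names, factor_names = factor_names),
                   class = "cfa_params")
  if (check_pd) {
    sigma <- implied_covariance(out)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(abs(ev)))
      stop("implied covariance is not positive definite (min eigenvalue ",
           format(min(ev)), ")")
  }
  out
}

#' Model-implied covariance matrix
#'
#' @param params A \code{cfa_params} parameter set.
#' @return The symmetric p x p matrix \eqn{\Lambda \Psi \Lambda' + \Theta}.
#' @export
implied_covariance <- function(params) {
  stopifnot(inherits(params, "cfa_params"))
  sigma <- params$lambda %*% params$psi %*% t(params$lambda) + params$theta
  (sigma + t(sigma)) / 2
}

#' Split a one-factor population into two correlated factors
#'
#' Builds the classic dimensionality misspecification: the single factor is
#' split into two factors with the stated correlation while loadings and
#' residual covariances are kept. The factor variance of the input is
#' preserved on both diagonal entries, so a correlation of 1 reproduces the
#' input's implied covariance exactly.
#'
#' @param pop A one-factor \code{cfa_params}.
#' @param item_partition List of two disjoint item-name (or index) vectors
#'   covering all items; the first set loads on the first new factor.
#' @param r Correlation between the two new factors, in (-1, 1].
#' @return A two-factor \code{cfa_params}.
#' @export
split_factor <- function(pop, item_partition, r) {
  stopifnot(inherits(pop, "cfa_params"))
  if (ncol(pop$lambda) != 1L) stop("split_factor requires a one-factor population model")
  if (!is.list(item_partition) || length(item_partition) != 2L)
    stop("item_partition must be a list of two item sets")
  part <- lapply(item_partition, function(g) {
    if (is.character(g)) {
      idx <- match(g, pop$item_names)
      if (anyNA(idx)) stop("unknown item(s): ", paste(g[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(g)
  })
  if (any(lengths(part) == 0L)) stop("empty partition cell")
  all_idx <- sort(unlist(part))
  if (!identical(all_idx, seq_along(pop$item_names)))
    stop("item_partition must cover all items disjointly")
  if (!is.numeric(r) || length(r) != 1L || r <= -1 || r > 1)
    stop("factor correlation r must lie in (-1, 1]")
  p <- nrow(pop$lambda)
  phi <- pop$psi[1, 1]
  lambda2 <- matrix(0, p, 2, dimnames = list(pop$item_names, c("g1", "g2")))
  lambda2[part[[1]], 1] <- pop$lambda[part[[1]], 1]
  lambda2[part[[2]], 2] <- pop$lambda[part[[2]], 1]
  psi2 <- matrix(phi * c(1, r, r, 1), 2, 2)
  parameter_set(lambda2, psi2, pop$theta, pop$item_names, c("g1", "g2"))
}

#' Add residual correlations to a population model
#'
#' Inserts residual covariances \eqn{\theta_{ij} = r \sqrt{\theta_{ii}\theta_{jj}}}
#' for the given item pairs, the standard "omitted correlated residuals"
#' misspecification; everything else is unchanged.
#'
#' @param pop A \code{cfa_params}.
#' @param pairs List of two-element item-name (or index) vectors, or a
#'   two-column matrix of pairs.
#' @param r Residual correlation applied to every pair (recycled if a vector
#'   of the same length as \code{pairs}).
#' @return A \code{cfa_params} with the modified residual covariance matrix.
#' @export
add_residual_correlations <- function(pop, pairs, r) {
  stopifnot(inherits(pop, "cfa_params"))
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  if (!length(pairs)) stop("no pairs supplied")
  r <- rep_len(r, length(pairs))
  if (any(abs(r) >= 1)) stop("residual correlation r must lie in (-1, 1)")
  theta <- pop$theta
  seen <- character(0)
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    if (length(pr) != 2L) stop("each pair must have exactly two items")
    idx <- if (is.character(pr)) match(pr, pop$item_names) else as.integer(pr)
    if (anyNA(idx)) stop("pair references unknown item: ", paste(pr[is.na(idx)], collapse = ", "))
    if (idx[1] == idx[2]) stop("pair must reference two distinct items")
    key <- paste(sort(idx), collapse = "-")
    if (key %in% seen) stop("duplicate pair: ", paste(pop$item_names[idx], collapse = ", "))
    seen <- c(seen, key)
    cov_ij <- r[k] * sqrt(theta[idx[1], idx[1]] * theta[idx[2], idx[2]])
    theta[idx[1], idx[2]] <- theta[idx[2], idx[1]] <- cov_ij
  }
  ev <- eigen((theta + t(theta)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("resulting residual covariance matrix is not positive definite")
  parameter_set(pop$lambda, pop$psi, theta, pop$item_names, pop$factor_names)
}

#' @export
print.cfa_params <- function(x, ...) {
  cat("CFA parameter set:", length(x$factor_names), "factor(s),",
      length(x$item_names), "items\n")
  cat("loadings (lambda):\n"); print(round(x$lambda, 3))
  cat("factor covariance (psi):\n"); print(round(x$psi, 3))
  nz <- sum(x$theta[lower.tri(x$theta)] != 0)
  cat("residual covariance (theta): diag ", paste(round(diag(x$theta), 3), collapse = ", "),
      if (nz > 0) paste0(" (+", nz, " off-diagonal)") else "", "\n", sep = "")
  invisible(x)
}
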