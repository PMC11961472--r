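# Fit indices evaluated by the cutoff-tailoring pipeline: chi-square (raw
# and mean-scaled), CFI, RMSEA (raw and scaled versions computed from the
# scaled statistic), and SRMR.

#' Comparative fit index (CFI)
#'
#' \eqn{CFI = 1 - \max(T - df, 0) / \max(T_b - df_b, T - df, 0)}, comparing
#' the model's excess statistic to that of the independence baseline. The
#' scaled version is obtained by passing the scaled statistics.
#'
#' @param T_stat,df Model test statistic and degrees of freedom.
#' @param T_b,df_b Baseline statistic and degrees of freedom.
#' @return CFI in \eqn{[0, 1]}.
#' @export
cfi <- function(T_stat, df, T_b, df_b) {
  if (df_b < df) stop("baseline df must be at least the model df")
  num <- max(T_stat - df, 0)
  den <- max(T_b - df_b, T_stat - df, 0)
  if (den == 0) return(1)   # degenerate baseline, no excess misfit anywhere
  1 - num / den
}

#' Root mean square error of approximation (RMSEA)
#'
#' \eqn{RMSEA = \sqrt{\max(T - df, 0) / (df \cdot n)}}; the denominator uses
#' the same multiplier convention as the test statistic. The scaled version
#' substitutes the mean-scaled statistic.
#'
#' @param T_stat Test statistic.
#' @param df Degrees of freedom; must be positive.
#' @param n Sample size.
#' @return RMSEA (non-negative), or \code{NA} with a warning when
#'   \code{df = 0}.
#' @export
rmsea <- function(T_stat, df, n) {
  if (df == 0) {
    warning("RMSEA is undefined for a saturated model (df = 0)")
    return(NA_real_)
  }
  stopifnot(n > 1)
  sqrt(max(T_stat - df, 0) / (df * n))
}

#' Standardized root mean square residual (SRMR)
#'
#' Square root of the mean squared standardized residual
#' \eqn{(s_{ij} - \hat\sigma_{ij}) / \sqrt{s_{ii} s_{jj}}} over the
#' \eqn{p(p+1)/2} unique covariance elements, diagonal included (covariance
#' version; no mean residuals).
#'
#' @param S Sample covariance matrix.
#' @param Sigma_hat Model-implied covariance matrix.
#' @return SRMR (non-negative).
#' @export
srmr <- function(S, Sigma_hat) {
  S <- as.matrix(S); Sigma_hat <- as.matrix(Sigma_hat)
  if (!all(dim(S) == dim(Sigma_hat))) stop("dimension mismatch between S and Sigma_hat")
  d <- diag(S)
  if (any(d <= 0)) stop("nonpositive variance on the diagonal of S")
  sd_out <- sqrt(d) %o% sqrt(d)
  res <- (S - Sigma_hat) / sd_out
  sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
}

#' Direction of each fit index
#'
#' @return Named logical vector: \code{TRUE} where higher values indicate
#'   better fit (CFI variants), \code{FALSE} where lower is better.
#' @export
index_directions <- function() {
  c(chisq = FALSE, chisq_scaled = FALSE,
    cfi = TRUE, cfi_scaled = TRUE,
    rmsea = FALSE, rmsea_scaled = FALSE,
    srmr = FALSE)
}

#' Compute the full fit-index set for one fitted model
#'
#' Populates chi-square (raw and scaled), CFI, RMSEA (raw/scaled) and SRMR
#' from a [fit_ml()]/[fit_cfa()] result. A non-converged fit yields a
#' sentinel row (all indices \code{NA}, \code{converged = FALSE}) that the
#' pipeline excludes downstream and counts.
#'
#' @param fit A \code{cfa_fit}.
#' @return One-row data frame with columns \code{converged}, \code{proper},
#'   \code{chisq}, \code{chisq_scaled}, \code{cfi}, \code{cfi_scaled},
#'   \code{rmsea}, \code{rmsea_scaled}, \code{srmr}, \code{df}.
#' @export
compute_fit_indices <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$converged) {
    return(data.frame(converged = FALSE, proper = fit$proper,
                      chisq = NA_real_, chisq_scaled = NA_real_,
                      cfi = NA_real_, cfi_scaled = NA_real_,
                      rmsea = NA_real_, rmsea_scaled = NA_real_,
                      srmr = NA_real_, df = fit$df))
  }
  c_m <- if (is.na(fit$c)) 1 else fit$c
  c_b <- if (is.null(fit$baseline_c) || is.na(fit$baseline_c)) 1 else fit$baseline_c
  Ts <- fit$T_stat / c_m
  Tbs <- fit$baseline_T / c_b
  rm_raw <- if (fit$df > 0) rmsea(fit$T_stat, fit$df, fit$n) else NA_real_
  rm_sc <- if (fit$df > 0) rmsea(Ts, fit$df, fit$n) else NA_real_
  data.frame(converged = TRUE, proper = fit$proper,
             chisq = fit$T_stat,
             chisq_scaled = Ts,
             cfi = cfi(fit$T_stat, fit$df, fit$baseline_T, fit$baseline_df),
             cfi_scaled = cfi(Ts, fit$df, Tbs, fit$baseline_df),
             rmsea = rm_raw,
             rmsea_scaled = rm_sc,
             srmr = srmr(fit$S, fit$Sigma_hat),
             df = fit$df)
}
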