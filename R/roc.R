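# ROC analysis of H0 vs. H1 fit-index distributions: curve, AUC, Youden
# cutoff, AUC-threshold screening. "Positive" means flagged as misspecified;
# a value exactly equal to the cutoff counts as passing (model accepted),
# matching the accept rules "chi-square <= cutoff" / "CFI >= cutoff".

#' Paired H0/H1 fit-index samples
#'
#' @param h0_values Index values from correctly specified (H0) fits.
#' @param h1_values Index values from misspecified (H1) fits.
#' @param higher_is_better Direction flag (\code{TRUE} for CFI variants).
#' @param index_name Label.
#' @return An object of class \code{index_distributions}.
#' @export
index_distributions <- function(h0_values, h1_values, higher_is_better = FALSE,
                                index_name = "index") {
  h0 <- as.numeric(h0_values[is.finite(h0_values)])
  h1 <- as.numeric(h1_values[is.finite(h1_values)])
  if (!length(h0) || !length(h1))
    stop("both H0 and H1 samples must be non-empty (index ", index_name, ")")
  structure(list(h0 = h0, h1 = h1,
                 higher_is_better = isTRUE(higher_is_better),
                 index_name = index_name),
            class = "index_distributions")
}

# confusion rates at one cutoff; positive = strictly on the worse-fit side
rates_at_cutoff <- function(dist, cutoff) {
  if (dist$higher_is_better) {
    tpr <- mean(dist$h1 < cutoff)
    fpr <- mean(dist$h0 < cutoff)
  } else {
    tpr <- mean(dist$h1 > cutoff)
    fpr <- mean(dist$h0 > cutoff)
  }
  c(tpr = tpr, fpr = fpr)
}

#' ROC curve over observed fit-index values
#'
#' Candidate cutoffs are the distinct observed values of the pooled H0/H1
#' sample; each yields a (false-positive rate, true-positive rate) point,
#' with sensitivity the share of misspecified (H1) fits flagged and
#' specificity the share of correct (H0) fits passed. Endpoints (0,0) and
#' (1,1) are appended and the AUC is the trapezoidal area.
#'
#' @param dist An [index_distributions()] object.
#' @return List of class \code{roc_curve}: \code{points} (data frame with
#'   \code{cutoff}, \code{fpr}, \code{tpr}, ordered by increasing fpr) and
#'   \code{auc}.
#' @export
roc_curve <- function(dist) {
  stopifnot(inherits(dist, "index_distributions"))
  cuts <- sort(unique(c(dist$h0, dist$h1)),
               decreasing = !dist$higher_is_better)
  # ordered so that fpr/tpr are non-decreasing along the sequence
  rr <- vapply(cuts, function(ct) rates_at_cutoff(dist, ct), c(tpr = 0, fpr = 0))
  pts <- data.frame(cutoff = c(NA, cuts, NA),
                    fpr = c(0, rr["fpr", ], 1),
                    tpr = c(0, rr["tpr", ], 1))
  o <- order(pts$fpr, pts$tpr)
  pts <- pts[o, , drop = FALSE]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, index_name = dist$index_name),
            class = "roc_curve")
}

#' Pairwise-concordance AUC (Mann-Whitney form)
#'
#' Independent check of the trapezoidal AUC: the fraction of (H1, H0) value
#' pairs in which the H1 value is strictly on the worse-fit side, counting
#' ties 0.5.
#'
#' @param dist An [index_distributions()] object.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_pairwise <- function(dist) {
  stopifnot(inherits(dist, "index_distributions"))
  h0 <- dist$h0; h1 <- dist$h1
  if (dist$higher_is_better) {
    worse <- outer(h1, h0, `<`); tie <- outer(h1, h0, `==`)
  } else {
    worse <- outer(h1, h0, `>`); tie <- outer(h1, h0, `==`)
  }
  (sum(worse) + 0.5 * sum(tie)) / (length(h0) * length(h1))
}

#' Youden-optimal tailored cutoff for one fit index
#'
#' Evaluates every distinct observed value as a cutoff and returns the one
#' maximizing the Youden index (sensitivity + specificity - 1). Ties are
#' broken toward higher specificity, then toward the more conservative
#' cutoff (the one accepting more models). A value equal to the cutoff
#' counts as passing, so the accept rule reads "index <= cutoff" for
#' lower-is-better indices and "index >= cutoff" for CFI.
#'
#' @param dist An [index_distributions()] object.
#' @param auc_threshold Screening threshold recorded in the report
#'   (default 0.80).
#' @return An object of class \code{cutoff_report}: \code{index_name},
#'   \code{auc}, \code{cutoff}, \code{comparator}, \code{sensitivity},
#'   \code{specificity}, \code{youden}, \code{accuracy}, \code{type1},
#'   \code{type2}, \code{passed_auc_threshold}, \code{flagged} (AUC below
#'   0.5: the index behaves contrary to expectation and no cutoff is
#'   endorsed).
#' @export
optimal_cutoff <- function(dist, auc_threshold = 0.80) {
  stopifnot(inherits(dist, "index_distributions"))
  auc <- roc_curve(dist)$auc
  cuts <- sort(unique(c(dist$h0, dist$h1)))
  rr <- t(vapply(cuts, function(ct) rates_at_cutoff(dist, ct), c(tpr = 0, fpr = 0)))
  sens <- rr[, "tpr"]; spec <- 1 - rr[, "fpr"]
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  if (length(best) > 1) {
    best <- best[spec[best] == max(spec[best])]
    if (length(best) > 1) {
      # more conservative = accepts more models
      best <- if (dist$higher_is_better) min(best) else max(best)
    }
  }
  n0 <- length(dist$h0); n1 <- length(dist$h1)
  tp <- sens[best] * n1; tn <- spec[best] * n0
  acc <- (tp + tn) / (n0 + n1)
  structure(list(index_name = dist$index_name,
                 auc = auc,
                 cutoff = cuts[best],
                 comparator = if (dist$higher_is_better) ">=" else "<=",
                 higher_is_better = dist$higher_is_better,
                 sensitivity = sens[best], specificity = spec[best],
                 youden = youden[best], accuracy = acc,
                 type1 = 1 - spec[best], type2 = 1 - sens[best],
                 n_h0 = n0, n_h1 = n1,
                 passed_auc_threshold = auc >= auc_threshold,
                 flagged = auc < 0.5),
            class = "cutoff_report")
}

#' Screen fit indices by AUC and pick the best performer
#'
#' Keeps indices whose AUC meets the threshold and identifies the
#' best-performing (highest-AUC) index among them; exactly tied top AUCs
#' are all flagged co-best. When no index passes, the misspecification may
#' be too weak to be detected in the scenario and no cutoffs are endorsed.
#'
#' @param reports List of \code{cutoff_report}s, one per index.
#' @param auc_threshold Minimum acceptable AUC (default 0.80).
#' @return List of class \code{index_screen}: \code{kept}, \code{discarded}
#'   (with reason), \code{best_index} (character vector, length > 1 on
#'   ties), \code{threshold}.
#' @export
screen_indices <- function(reports, auc_threshold = 0.80) {
  stopifnot(length(reports) >= 1)
  names(reports) <- vapply(reports, `[[`, "", "index_name")
  aucs <- vapply(reports, `[[`, 0, "auc")
  keep <- aucs >= auc_threshold
  kept <- reports[keep]
  for (i in seq_along(kept)) kept[[i]]$passed_auc_threshold <- TRUE
  discarded <- lapply(reports[!keep], function(r) {
    r$passed_auc_threshold <- FALSE
    r$reason <- "AUC below threshold"
    r
  })
  best <- character(0)
  if (length(kept)) {
    kept_auc <- vapply(kept, `[[`, 0, "auc")
    best <- names(kept)[kept_auc == max(kept_auc)]
  } else {
    warning("no fit index reached the AUC threshold of ", auc_threshold,
            "; the misspecification might not be strong enough to be detected ",
            "in this scenario, and no cutoffs are endorsed")
  }
  structure(list(kept = kept, discarded = discarded, best_index = best,
                 threshold = auc_threshold),
            class = "index_screen")
}

#' Does an empirical index value pass a tailored cutoff?
#'
#' Boundary values count as passing.
#'
#' @param report A \code{cutoff_report}.
#' @param value Empirical fit-index value.
#' @return \code{TRUE} if the value is on the acceptable side of the cutoff.
#' @export
passes_cutoff <- function(report, value) {
  if (report$higher_is_better) value >= report$cutoff else value <= report$cutoff
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("%s: AUC = %.3f, cutoff %s %.4g | accuracy %.3f, type I %.3f, type II %.3f%s\n",
              x$index_name, x$auc, x$comparator, x$cutoff,
              x$accuracy, x$type1, x$type2,
              if (x$flagged) " [flagged: AUC < .5]" else ""))
  invisible(x)
}

#' @export
print.index_screen <- function(x, ...) {
  cat("Fit-index screening (AUC threshold ", x$threshold, "):\n", sep = "")
  for (r in x$kept) { cat("  kept   "); print(r) }
  for (r in x$discarded)
    cat(sprintf("  dropped %s: AUC = %.3f (%s)\n", r$index_name, r$auc, r$reason))
  if (length(x$best_index))
    cat("  best-performing:", paste(x$best_index, collapse = ", "),
        if (length(x$best_index) > 1) "(tied)" else "", "\n")
  invisible(x)
}
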