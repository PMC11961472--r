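# Diagnostic graphics: ROC curves of the screened indices and the overlaid
# H0/H1 fit-index distributions with the tailored cutoff.

#' Plot ROC curves for the fit indices of a study
#'
#' @param report A [run_study()] result.
#' @param kept_only Plot only indices that passed the AUC screen.
#' @return A ggplot object.
#' @export
plot_roc <- function(report, kept_only = TRUE) {
  stopifnot(inherits(report, "study_report"))
  reports <- if (kept_only && length(report$screen$kept))
    report$screen$kept else c(report$screen$kept, report$screen$discarded)
  dirs <- index_directions()
  tabs <- lapply(reports, function(r) {
    ix <- r$index_name
    dist <- index_distributions(
      usable_values(report$replicates[report$replicates$population == "H0", ], ix,
                    report$config$drop_improper),
      usable_values(report$replicates[report$replicates$population != "H0", ], ix,
                    report$config$drop_improper),
      higher_is_better = dirs[[ix]], index_name = ix)
    pts <- roc_curve(dist)$points
    pts$index <- sprintf("%s (AUC = %.2f)", ix, r$auc)
    pts
  })
  df <- do.call(rbind, tabs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   linetype = .data$index)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, colour = "grey70") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  linetype = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot H0/H1 fit-index distributions with the tailored cutoff
#'
#' Overlaid histograms of the index values from correctly specified (H0)
#' and misspecified (H1) replicates; the dashed vertical line marks the
#' Youden-optimal cutoff.
#'
#' @param report A [run_study()] result.
#' @param index Fit index to plot (default: the best-performing one).
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_index_distributions <- function(report, index = NULL, bins = 40) {
  stopifnot(inherits(report, "study_report"))
  if (is.null(index)) {
    if (!length(report$best_index)) stop("no index passed the screen; specify `index`")
    index <- report$best_index[1]
  }
  tab <- report$replicates
  df <- data.frame(
    value = tab[[index]],
    population = ifelse(tab$population == "H0", "correctly specified (H0)",
                        "misspecified (H1)"))
  df <- df[is.finite(df$value), ]
  all_reports <- c(report$screen$kept, report$screen$discarded)
  rep_ix <- all_reports[[match(index, vapply(all_reports, `[[`, "", "index_name"))]]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$population)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55, position = "identity") +
    ggplot2::scale_fill_manual(values = c("grey75", "grey30")) +
    ggplot2::labs(x = index, y = "replicates", fill = NULL) +
    ggplot2::theme_minimal()
  if (isTRUE(rep_ix$passed_auc_threshold))
    g <- g + ggplot2::geom_vline(xintercept = rep_ix$cutoff, linetype = "dashed")
  g
}

#' Write study outputs to a directory
#'
#' Writes \code{replicates.csv} (per-replicate fit-index table),
#' \code{cutoffs.json}, \code{report.json}, a human-readable
#' \code{report.md}, and \code{roc.png} / \code{dist_<index>.png}.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @param plots Also write PNG figures.
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir, plots = TRUE) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$cutoffs, file.path(dir, "cutoffs.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  summary_list <- list(
    verdict = report$verdict, rationale = report$rationale,
    best_index = report$best_index,
    auc_threshold = report$config$auc_threshold,
    estimator = report$config$estimator,
    n = report$config$sim$n, n_reps = report$config$sim$n_reps,
    master_seed = report$config$sim$master_seed,
    rates = report$rates,
    empirical_indices = report$empirical_indices,
    misfit_effect = if (!is.null(report$misfit_effect))
      report$misfit_effect[c("F0", "pop_rmsea", "pop_chisq_per_df")] else NULL)
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  md <- c(paste("# Tailored-cutoff study report"), "",
          utils::capture.output(print(report)))
  writeLines(md, file.path(dir, "report.md"))
  if (plots) {
    ggplot2::ggsave(file.path(dir, "roc.png"), plot_roc(report, kept_only = FALSE),
                    width = 6, height = 5, dpi = 120)
    for (r in report$screen$kept) {
      ggplot2::ggsave(file.path(dir, paste0("dist_", r$index_name, ".png")),
                      plot_index_distributions(report, r$index_name),
                      width = 6, height = 4, dpi = 120)
    }
  }
  invisible(dir)
}
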