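# Orchestration: empirical fit -> twin Monte Carlo simulations under the H0
# and H1 population models -> per-replicate fit-index table -> ROC screening
# and tailored cutoffs -> accept/reject decision for the empirical model.

#' Study configuration for the cutoff-tailoring pipeline
#'
#' @param analysis_model A \code{cfa_model} (the model whose fit is tested).
#' @param h0_population A \code{cfa_params} population under which the
#'   analysis model is correctly specified, or \code{"from_empirical_fit"}
#'   to use the structure and parameter estimates of the empirical fit
#'   (requires \code{empirical_data}).
#' @param h1_populations A \code{cfa_params} or list of them: population
#'   model(s) under which the analysis model is misspecified to an
#'   intolerable degree. The first is the primary H1; additional ones are
#'   used by [robustness_check()].
#' @param sim A [sim_config()]. Its \code{margins} may be
#'   \code{"empirical"} to match the per-item skewness/excess kurtosis of
#'   the empirical data (the default when data are supplied).
#' @param estimator \code{"MLR"} (default) or \code{"ML"}.
#' @param indices Character vector of fit indices to evaluate; defaults to
#'   the scaled statistic family plus SRMR under MLR, and the raw family
#'   under ML.
#' @param auc_threshold AUC screening threshold (default 0.80).
#' @param empirical_data Optional n x p matrix/data frame (or CSV path) of
#'   item responses.
#' @param drop_improper Exclude improper (Heywood) solutions from the
#'   distributions (default \code{FALSE}: they are retained, counted and
#'   reported).
#' @return An object of class \code{study_config}.
#' @export
study_config <- function(analysis_model, h0_population, h1_populations, sim,
                         estimator = c("MLR", "ML"), indices = NULL,
                         auc_threshold = 0.80, empirical_data = NULL,
                         drop_improper = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(analysis_model, "cfa_model"), inherits(sim, "sim_config"))
  if (inherits(h1_populations, "cfa_params")) h1_populations <- list(h1_populations)
  if (!length(h1_populations)) stop("at least one H1 population model is required")
  for (h1 in h1_populations) stopifnot(inherits(h1, "cfa_params"))
  from_fit <- identical(h0_population, "from_empirical_fit")
  if (!from_fit) stopifnot(inherits(h0_population, "cfa_params"))
  if (is.character(empirical_data) && length(empirical_data) == 1L)
    empirical_data <- utils::read.csv(empirical_data)
  if (from_fit && is.null(empirical_data))
    stop("h0_population = \"from_empirical_fit\" requires empirical_data")
  if (is.null(indices)) {
    indices <- if (estimator == "MLR")
      c("chisq_scaled", "cfi_scaled", "rmsea_scaled", "srmr")
    else c("chisq", "cfi", "rmsea", "srmr")
  }
  stopifnot(all(indices %in% names(index_directions())))
  structure(list(analysis_model = analysis_model,
                 h0_population = h0_population,
                 h1_populations = h1_populations,
                 sim = sim, estimator = estimator, indices = indices,
                 auc_threshold = auc_threshold,
                 empirical_data = if (is.null(empirical_data)) NULL else as.matrix(empirical_data),
                 drop_improper = isTRUE(drop_improper)),
            class = "study_config")
}

# parameter estimates of a fit, reused as an H0 population model
population_from_fit <- function(fit) {
  if (!fit$converged) stop("empirical fit did not converge; cannot derive an H0 population")
  if (!fit$proper)
    warning("empirical solution is improper (Heywood case); the derived H0 population may be invalid")
  parameter_set(fit$params$lambda, fit$params$psi, fit$params$theta,
                fit$params$item_names, fit$params$factor_names)
}

# fit all replicates from one population; returns a per-replicate index table
simulate_index_table <- function(pop, label, cfg, progress = interactive()) {
  setup <- vm_setup(pop, cfg$sim$margins)
  rows <- vector("list", cfg$sim$n_reps)
  for (r in seq_len(cfg$sim$n_reps)) {
    x <- vm_draw(setup, cfg$sim$n, replicate_seed(cfg$sim$master_seed, label, r))
    fit <- tryCatch(fit_cfa(cfg$analysis_model, x, estimator = cfg$estimator),
                    error = function(e) NULL)
    row <- if (is.null(fit)) {
      data.frame(converged = FALSE, proper = NA,
                 chisq = NA_real_, chisq_scaled = NA_real_, cfi = NA_real_,
                 cfi_scaled = NA_real_, rmsea = NA_real_, rmsea_scaled = NA_real_,
                 srmr = NA_real_, df = cfg$analysis_model$df)
    } else compute_fit_indices(fit)
    rows[[r]] <- cbind(population = label, rep = r, row)
    if (progress && r %% 50 == 0)
      message(label, ": ", r, "/", cfg$sim$n_reps, " replicates")
  }
  do.call(rbind, rows)
}

usable_values <- function(tab, index, drop_improper) {
  ok <- tab$converged & is.finite(tab[[index]])
  if (drop_improper) ok <- ok & tab$proper %in% TRUE
  tab[[index]][ok]
}

# Step 2 + 3 for one H0/H1 replicate-table pair
cutoffs_from_tables <- function(h0_tab, h1_tab, indices, auc_threshold, drop_improper) {
  dirs <- index_directions()
  reports <- lapply(indices, function(ix) {
    dist <- index_distributions(usable_values(h0_tab, ix, drop_improper),
                                usable_values(h1_tab, ix, drop_improper),
                                higher_is_better = dirs[[ix]], index_name = ix)
    optimal_cutoff(dist, auc_threshold = auc_threshold)
  })
  names(reports) <- indices
  screen_indices(reports, auc_threshold = auc_threshold)
}

decide_verdict <- function(screen, empirical_indices) {
  kept <- screen$kept
  if (!length(kept))
    return(list(verdict = "indeterminate",
                rationale = paste("No fit index reached the AUC threshold;",
                                  "the misspecification might not be strong enough",
                                  "to be detected in this scenario.")))
  if (is.null(empirical_indices))
    return(list(verdict = NA_character_,
                rationale = "No empirical data supplied; cutoffs generated only."))
  passes <- vapply(kept, function(r) passes_cutoff(r, empirical_indices[[r$index_name]]), NA)
  if (all(passes))
    return(list(verdict = "accept",
                rationale = "All retained fit indices pass their tailored cutoffs."))
  if (!any(passes))
    return(list(verdict = "reject",
                rationale = "All retained fit indices fail their tailored cutoffs."))
  best <- screen$best_index
  best_pass <- passes[best]
  if (length(unique(best_pass)) > 1)
    return(list(verdict = "indeterminate",
                rationale = paste("Fit indices disagree and the tied best-performing",
                                  "indices disagree as well; no decision is endorsed.")))
  v <- if (all(best_pass)) "accept" else "reject"
  list(verdict = v,
       rationale = paste0("Fit indices disagree; prioritizing the best-performing index (",
                          paste(best, collapse = ", "), ", AUC = ",
                          paste(sprintf("%.3f", vapply(kept[best], `[[`, 0, "auc")), collapse = ", "),
                          "), which ", if (v == "accept") "passes" else "fails",
                          " its cutoff."))
}

#' Run a full tailored-cutoff study
#'
#' Executes the three-step procedure: (1) simulate \code{n_reps} datasets
#' from the H0 and (primary) H1 population models and fit the analysis model
#' to each; (2) rank the fit indices by the AUC of their H0/H1 distributions
#' and screen at the AUC threshold; (3) report Youden-optimal tailored
#' cutoffs with accuracy and type I/II error rates. When empirical data are
#' supplied, the empirical fit-index values are judged against the cutoffs:
#' accept if every retained index passes, reject if every one fails,
#' otherwise the best-performing index decides; indeterminate when no index
#' survives screening.
#'
#' @param cfg A [study_config()].
#' @param progress Emit progress messages every 50 replicates.
#' @return An object of class \code{study_report}: \code{empirical_fit},
#'   \code{empirical_indices}, \code{replicates} (per-replicate index
#'   table), \code{screen} (kept/discarded cutoff reports),
#'   \code{cutoffs} (data-frame summary), \code{verdict}, \code{rationale},
#'   \code{rates} (convergence/propriety by population),
#'   \code{misfit_effect} (population-level effect size of the primary H1),
#'   and the \code{config}.
#' @export
run_study <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "study_config"))

  empirical_fit <- NULL; empirical_indices <- NULL
  if (!is.null(cfg$empirical_data)) {
    empirical_fit <- fit_cfa(cfg$analysis_model, cfg$empirical_data,
                             estimator = cfg$estimator)
    empirical_indices <- compute_fit_indices(empirical_fit)
    if (identical(cfg$sim$margins, "empirical"))
      cfg$sim$margins <- estimate_margins(cfg$empirical_data)
  }
  if (identical(cfg$sim$margins, "empirical"))
    stop("margins = \"empirical\" requires empirical_data")
  h0 <- if (identical(cfg$h0_population, "from_empirical_fit"))
    population_from_fit(empirical_fit) else cfg$h0_population
  h1 <- cfg$h1_populations[[1]]

  h0_tab <- simulate_index_table(h0, "H0", cfg, progress)
  h1_tab <- simulate_index_table(h1, "H1", cfg, progress)
  for (tab in list(H0 = h0_tab, H1 = h1_tab)) {
    nc <- mean(!tab$converged)
    if (nc > 0.20)
      stop("more than 20% of replicates failed to converge under ",
           tab$population[1], " (", round(100 * nc, 1),
           "%); check the population model and sample size")
  }

  screen <- cutoffs_from_tables(h0_tab, h1_tab, cfg$indices,
                                cfg$auc_threshold, cfg$drop_improper)
  decision <- decide_verdict(screen, empirical_indices)

  rates <- do.call(rbind, lapply(list(h0_tab, h1_tab), function(tab) {
    data.frame(population = tab$population[1],
               convergence_rate = mean(tab$converged),
               propriety_rate = mean(tab$proper %in% TRUE))
  }))

  misfit <- tryCatch(
    quantify_misspecification(cfg$analysis_model, h1, cfg$sim$n),
    error = function(e) NULL)

  all_reports <- c(screen$kept, screen$discarded)
  cutoffs <- do.call(rbind, lapply(all_reports, function(r) {
    data.frame(index = r$index_name, auc = r$auc,
               kept = r$passed_auc_threshold,
               cutoff = if (r$passed_auc_threshold) r$cutoff else NA_real_,
               comparator = r$comparator, accuracy = r$accuracy,
               type1 = r$type1, type2 = r$type2, flagged = r$flagged)
  }))
  rownames(cutoffs) <- NULL

  structure(list(empirical_fit = empirical_fit,
                 empirical_indices = empirical_indices,
                 replicates = rbind(h0_tab, h1_tab),
                 screen = screen, cutoffs = cutoffs,
                 best_index = screen$best_index,
                 verdict = decision$verdict, rationale = decision$rationale,
                 rates = rates, misfit_effect = misfit, config = cfg),
            class = "study_report")
}

#' Population-level misspecification effect size
#'
#' Fits the analysis model to the population covariance implied by
#' \code{pop} (no sampling) and reports the population minimized discrepancy
#' \eqn{F_0}, the population RMSEA \eqn{\sqrt{F_0/df}}, and the
#' noncentrality-per-df analogue \eqn{1 + n F_0 / df} (the expected
#' chi-square/df ratio at sample size n). \eqn{F_0 = 0} exactly when the
#' analysis model reproduces the population covariance.
#'
#' @param analysis A \code{cfa_model}.
#' @param pop A \code{cfa_params} population model.
#' @param n Reference sample size for the chi-square/df analogue.
#' @return List of class \code{misfit_effect}: \code{F0}, \code{pop_rmsea},
#'   \code{pop_chisq_per_df}.
#' @export
quantify_misspecification <- function(analysis, pop, n) {
  stopifnot(inherits(analysis, "cfa_model"), inherits(pop, "cfa_params"))
  sigma <- implied_covariance(pop)
  fit <- fit_ml(analysis, sigma, n = n)
  if (!fit$converged) stop("population-level minimization did not converge")
  F0 <- if (fit$F_min < 1e-10) 0 else fit$F_min
  structure(list(F0 = F0,
                 pop_rmsea = if (analysis$df > 0) sqrt(F0 / analysis$df) else NA_real_,
                 pop_chisq_per_df = if (analysis$df > 0) 1 + n * F0 / analysis$df else NA_real_,
                 df = analysis$df, n = n),
            class = "misfit_effect")
}

#' Robustness check over multiple H1 misspecification forms
#'
#' Repeats the screening and cutoff generation (Steps 2-3) for each H1
#' population model, sharing the H0 simulations, and summarises whether the
#' accept/reject verdict agrees across the misspecification forms. Warns
#' when the population discrepancies of the forms differ by more than a
#' factor of two, since the forms should represent roughly the same degree
#' of misspecification.
#'
#' @param cfg A [study_config()] with two or more \code{h1_populations}
#'   (a single H1 reduces to [run_study()]).
#' @param progress Emit progress messages.
#' @return List of class \code{robustness_report}: \code{per_h1} (one
#'   screen + verdict per form), \code{misfit_effects}, \code{agreement}
#'   (logical), \code{verdicts}.
#' @export
robustness_check <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "study_config"))
  n_h1 <- length(cfg$h1_populations)

  empirical_fit <- NULL; empirical_indices <- NULL
  if (!is.null(cfg$empirical_data)) {
    empirical_fit <- fit_cfa(cfg$analysis_model, cfg$empirical_data,
                             estimator = cfg$estimator)
    empirical_indices <- compute_fit_indices(empirical_fit)
    if (identical(cfg$sim$margins, "empirical"))
      cfg$sim$margins <- estimate_margins(cfg$empirical_data)
  }
  h0 <- if (identical(cfg$h0_population, "from_empirical_fit"))
    population_from_fit(empirical_fit) else cfg$h0_population

  h0_tab <- simulate_index_table(h0, "H0", cfg, progress)
  misfits <- lapply(cfg$h1_populations, function(h1)
    tryCatch(quantify_misspecification(cfg$analysis_model, h1, cfg$sim$n),
             error = function(e) NULL))
  F0s <- vapply(misfits, function(m) if (is.null(m)) NA_real_ else m$F0, 0)
  if (n_h1 >= 2 && all(is.finite(F0s)) && all(F0s > 0) &&
      max(F0s) / min(F0s) > 2)
    warning("the H1 forms represent different degrees of misspecification ",
            "(population discrepancies differ by more than a factor of 2); ",
            "their cutoffs are not directly comparable")

  per_h1 <- vector("list", n_h1)
  verdicts <- character(n_h1)
  for (k in seq_len(n_h1)) {
    label <- paste0("H1_", k)
    h1_tab <- simulate_index_table(cfg$h1_populations[[k]], label, cfg, progress)
    screen <- cutoffs_from_tables(h0_tab, h1_tab, cfg$indices,
                                  cfg$auc_threshold, cfg$drop_improper)
    decision <- decide_verdict(screen, empirical_indices)
    per_h1[[k]] <- list(label = label, screen = screen,
                        verdict = decision$verdict, rationale = decision$rationale)
    verdicts[k] <- decision$verdict
  }
  known <- verdicts[!is.na(verdicts)]
  structure(list(per_h1 = per_h1, misfit_effects = misfits,
                 verdicts = verdicts,
                 agreement = length(unique(known)) <= 1),
            class = "robustness_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Tailored-cutoff study (", x$config$estimator, ", N = ", x$config$sim$n,
      ", ", x$config$sim$n_reps, " reps per population)\n", sep = "")
  print(x$rates, row.names = FALSE)
  cat("\n")
  print(x$screen)
  if (!is.null(x$empirical_indices)) {
    cat("\nEmpirical fit-index values:\n")
    keep <- intersect(x$config$indices, names(x$empirical_indices))
    print(round(x$empirical_indices[keep], 4), row.names = FALSE)
  }
  if (!is.null(x$misfit_effect))
    cat(sprintf("\nH1 misspecification effect size: F0 = %.4f, population RMSEA = %.4f\n",
                x$misfit_effect$F0, x$misfit_effect$pop_rmsea))
  if (!is.na(x$verdict)) cat("\nVerdict:", toupper(x$verdict), "-", x$rationale, "\n")
  invisible(x)
}

#' @export
print.misfit_effect <- function(x, ...) {
  cat(sprintf("Population misfit: F0 = %.5f, RMSEA = %.4f, chi-square/df analogue = %.2f (df = %d, n = %d)\n",
              x$F0, x$pop_rmsea, x$pop_chisq_per_df, x$df, as.integer(x$n)))
  invisible(x)
}
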