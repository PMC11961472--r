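#' Parse a CFA model-definition string
#'
#' Parses a small dialect of the de-facto SEM model syntax into a structured
#' CFA analysis model. Two operators are supported: \code{=~} ("is measured
#' by": the left-hand factor loads on the right-hand items) and \code{~~}
#' (a variance or covariance between two items or two factors). A numeric
#' premultiplier fixes a parameter, e.g. \code{"f1 ~~ 0.7*f2"} fixes the
#' factor covariance to 0.7 and \code{"f1 =~ 1*x1"} fixes a loading to 1.
#' Statements are separated by newlines (or \code{;}); \code{#} starts a
#' comment. The regression operator \code{~} is reserved and rejected.
#'
#' Defaults follow common CFA practice: residual variances are free, residual
#' covariances are fixed to zero unless declared, and factor covariances are
#' free. Identification is by a marker loading (first listed item of each
#' factor fixed to 1, factor variances free) or by unit factor variances
#' (all loadings free, factor variances fixed to 1).
#'
#' @param text Model definition string (possibly multi-line).
#' @param identification \code{"marker_loading"} (default) or
#'   \code{"unit_factor_variance"}.
#' @return An object of class \code{cfa_model}: the free/fixed pattern and
#'   fixed values for the loading matrix (lambda), factor covariance matrix
#'   (psi) and residual covariance matrix (theta), plus item/factor names,
#'   the free-parameter count \code{q} and the degrees of freedom
#'   \code{df = p(p+1)/2 - q}.
#' @examples
#' m <- parse_model("f1 =~ x1 + x2 + x3 + x4 + x5")
#' m$df   # 5
#' @export
parse_model <- function(text, identification = c("marker_loading", "unit_factor_variance")) {
  identification <- match.arg(identification)
  stopifnot(is.character(text), length(text) >= 1L)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  statements <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (!nzchar(s)) next
    if (grepl("=~", s, fixed = TRUE)) {
      parts <- strsplit(s, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("syntax error at line ", ln, ": malformed '=~' statement: ", s)
      statements[[length(statements) + 1L]] <-
        list(op = "=~", lhs = trimws(parts[1]), rhs = trimws(parts[2]), line = ln)
    } else if (grepl("~~", s, fixed = TRUE)) {
      parts <- strsplit(s, "~~", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("syntax error at line ", ln, ": malformed '~~' statement: ", s)
      statements[[length(statements) + 1L]] <-
        list(op = "~~", lhs = trimws(parts[1]), rhs = trimws(parts[2]), line = ln)
    } else if (grepl("~", s, fixed = TRUE)) {
      stop("syntax error at line ", ln, ": regression operator '~' is reserved and not supported; ",
           "only '=~' and '~~' are allowed")
    } else {
      stop("syntax error at line ", ln, ": no operator found in: ", s)
    }
  }
  if (!length(statements)) stop("empty model definition")

  # one term "coef*name" or "name"
  parse_term <- function(term, line) {
    term <- trimws(term)
    if (!nzchar(term)) stop("syntax error at line ", line, ": empty term")
    if (grepl("*", term, fixed = TRUE)) {
      pieces <- trimws(strsplit(term, "*", fixed = TRUE)[[1]])
      if (length(pieces) != 2L) stop("syntax error at line ", line, ": malformed premultiplier in '", term, "'")
      val <- suppressWarnings(as.numeric(pieces[1]))
      if (is.na(val)) stop("syntax error at line ", line, ": premultiplier '", pieces[1], "' is not numeric")
      list(name = pieces[2], fixed = TRUE, value = val)
    } else {
      list(name = term, fixed = FALSE, value = NA_real_)
    }
  }
  check_name <- function(nm, line) {
    if (!grepl("^[A-Za-z._][A-Za-z0-9._]*$", nm))
      stop("syntax error at line ", line, ": invalid name '", nm, "'")
    nm
  }

  loading_stmts <- Filter(function(s) s$op == "=~", statements)
  cov_stmts <- Filter(function(s) s$op == "~~", statements)
  if (!length(loading_stmts)) stop("model has no '=~' statement: no factor is defined")

  factors <- character(0)
  loadings <- list()  # list of (factor, item, fixed, value)
  for (s in loading_stmts) {
    f <- check_name(s$lhs, s$line)
    factors <- union(factors, f)
    terms <- strsplit(s$rhs, "+", fixed = TRUE)[[1]]
    if (!length(terms)) stop("unidentified factor '", f, "': no items (line ", s$line, ")")
    for (tm in terms) {
      t <- parse_term(tm, s$line)
      check_name(t$name, s$line)
      loadings[[length(loadings) + 1L]] <- list(factor = f, item = t$name,
                                               fixed = t$fixed, value = t$value, line = s$line)
    }
  }
  items <- unique(vapply(loadings, `[[`, "", "item"))
  if (any(items %in% factors)) {
    bad <- intersect(items, factors)
    stop("name used as both factor and item: ", paste(bad, collapse = ", "))
  }
  p <- length(items); m <- length(factors)

  lambda_free <- matrix(FALSE, p, m, dimnames = list(items, factors))
  lambda_value <- matrix(0, p, m, dimnames = list(items, factors))
  seen_loading <- matrix(FALSE, p, m)
  for (l in loadings) {
    i <- match(l$item, items); j <- match(l$factor, factors)
    if (seen_loading[i, j])
      stop("duplicate parameter at line ", l$line, ": loading of '", l$item, "' on '", l$factor, "'")
    seen_loading[i, j] <- TRUE
    if (l$fixed) {
      lambda_value[i, j] <- l$value
    } else {
      lambda_free[i, j] <- TRUE
    }
  }

  # theta defaults: diagonal free, off-diagonal fixed at 0
  theta_free <- diag(p) == 1
  theta_value <- matrix(0, p, p)
  dimnames(theta_free) <- dimnames(theta_value) <- list(items, items)
  # psi defaults: off-diagonal free; diagonal depends on identification
  psi_free <- matrix(TRUE, m, m, dimnames = list(factors, factors))
  psi_value <- matrix(0, m, m, dimnames = list(factors, factors))
  if (identification == "unit_factor_variance") {
    diag(psi_free) <- FALSE
    diag(psi_value) <- 1
  }

  seen_cov <- matrix(FALSE, p + m, p + m)  # items then factors
  all_names <- c(items, factors)
  for (s in cov_stmts) {
    lhs <- check_name(s$lhs, s$line)
    t <- parse_term(s$rhs, s$line)
    rhs <- check_name(t$name, s$line)
    li <- match(lhs, all_names); ri <- match(rhs, all_names)
    if (is.na(li)) stop("unknown name '", lhs, "' at line ", s$line,
                        if (!lhs %in% items) " (items must appear in a '=~' statement)" else "")
    if (is.na(ri)) stop("unknown name '", rhs, "' at line ", s$line,
                        if (!rhs %in% items) " (items must appear in a '=~' statement)" else "")
    both_items <- lhs %in% items && rhs %in% items
    both_factors <- lhs %in% factors && rhs %in% factors
    if (!both_items && !both_factors)
      stop("'~~' between an item and a factor is not supported (line ", s$line, ")")
    a <- min(li, ri); b <- max(li, ri)
    if (seen_cov[a, b]) stop("duplicate parameter at line ", s$line, ": ", lhs, " ~~ ", rhs)
    seen_cov[a, b] <- TRUE
    if (both_items) {
      i <- match(lhs, items); j <- match(rhs, items)
      if (t$fixed) {
        theta_free[i, j] <- theta_free[j, i] <- FALSE
        theta_value[i, j] <- theta_value[j, i] <- t$value
      } else {
        theta_free[i, j] <- theta_free[j, i] <- TRUE
      }
    } else {
      i <- match(lhs, factors); j <- match(rhs, factors)
      if (t$fixed) {
        psi_free[i, j] <- psi_free[j, i] <- FALSE
        psi_value[i, j] <- psi_value[j, i] <- t$value
      } else {
        psi_free[i, j] <- psi_free[j, i] <- TRUE
      }
    }
  }

  # marker identification: fix first listed loading of each factor to 1
  # unless the user already fixed a loading on that factor
  if (identification == "marker_loading") {
    for (j in seq_len(m)) {
      declared <- which(seen_loading[, j])
      has_fixed <- any(!lambda_free[declared, j] & seen_loading[declared, j])
      if (!has_fixed) {
        first <- declared[1L]
        lambda_free[first, j] <- FALSE
        lambda_value[first, j] <- 1
      }
    }
  }

  model <- structure(list(
    items = items, factors = factors,
    lambda_free = lambda_free, lambda_value = lambda_value,
    psi_free = psi_free, psi_value = psi_value,
    theta_free = theta_free, theta_value = theta_value,
    identification = identification
  ), class = "cfa_model")
  model$p <- p
  model$q <- n_free_parameters(model)
  model$df <- p * (p + 1) / 2 - model$q
  if (model$df < 0)
    stop("model is not identified: ", model$q, " free parameters exceed the ",
         p * (p + 1) / 2, " covariance moments (t-rule)")
  model
}

# free parameters: all lambda cells + lower triangle (incl. diagonal) of psi, theta
n_free_parameters <- function(model) {
  m <- length(model$factors)
  p <- length(model$items)
  sum(model$lambda_free) +
    sum(model$psi_free[lower.tri(model$psi_free, diag = TRUE)]) +
    sum(model$theta_free[lower.tri(model$theta_free, diag = TRUE)])
}

#' Serialize a CFA model back to model-definition syntax
#'
#' Inverse of [parse_model()]: the returned string parses back to an
#' identical free/fixed pattern (round-trip property).
#'
#' @param model A \code{cfa_model}.
#' @return A single model-definition string.
#' @export
serialize_model <- function(model) {
  stopifnot(inherits(model, "cfa_model"))
  out <- character(0)
  for (j in seq_along(model$factors)) {
    declared <- which(model$lambda_free[, j] | model$lambda_value[, j] != 0)
    terms <- vapply(declared, function(i) {
      if (model$lambda_free[i, j]) model$items[i]
      else paste0(format(model$lambda_value[i, j]), "*", model$items[i])
    }, "")
    out <- c(out, paste(model$factors[j], "=~", paste(terms, collapse = " + ")))
  }
  # non-default covariance statements
  p <- model$p; m <- length(model$factors)
  for (i in seq_len(p)) for (j in seq_len(i)) {
    if (i == j) {
      if (!model$theta_free[i, i])
        out <- c(out, paste0(model$items[i], " ~~ ", format(model$theta_value[i, i]), "*", model$items[i]))
    } else if (model$theta_free[i, j]) {
      out <- c(out, paste(model$items[j], "~~", model$items[i]))
    } else if (model$theta_value[i, j] != 0) {
      out <- c(out, paste0(model$items[j], " ~~ ", format(model$theta_value[i, j]), "*", model$items[i]))
    }
  }
  unit_var <- model$identification == "unit_factor_variance"
  for (i in seq_len(m)) for (j in seq_len(i)) {
    if (i == j) {
      if (!model$psi_free[i, i] && !unit_var)
        out <- c(out, paste0(model$factors[i], " ~~ ", format(model$psi_value[i, i]), "*", model$factors[i]))
    } else if (!model$psi_free[i, j]) {
      out <- c(out, paste0(model$factors[j], " ~~ ", format(model$psi_value[i, j]), "*", model$factors[i]))
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat("CFA analysis model:", length(x$factors), "factor(s),", x$p, "items\n")
  cat("  identification:", x$identification, "\n")
  cat("  free parameters q =", x$q, ", df =", x$df, "\n")
  invisible(x)
}
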