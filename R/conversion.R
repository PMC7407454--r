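#' Fit the SNP conversion-success model
#'
#' Binomial logistic regression of per-SNP conversion (1 = the tiled SNP
#' yielded usable genotypes) on binary design covariates — by default
#' `affy` (design-score recommendation), `canine`, `goldengate`, `sanger`
#' (pre-validation sources), `unique` (unique complete genomic mapping) and
#' `rad` (RAD origin). Fitted by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations) with Wald z tests
#' per term.
#'
#' @param design data.frame with a 0/1 `converted` column and 0/1 predictor
#'   columns.
#' @param predictors predictor column names; default: every column except
#'   `converted`. Constant (degenerate) predictors are dropped with a
#'   warning.
#' @return object of class `conversion_fit`: coefficient table, the glm
#'   fit, convergence flag and iteration count.
#' @export
fit_logistic <- function(design, predictors = setdiff(names(design), "converted")) {
  stopifnot("converted" %in% names(design))
  y <- design$converted
  if (!all(y %in% c(0, 1))) stop("converted must be 0/1")
  if (length(unique(y)) < 2L)
    stop("need both response levels to fit the model")
  keep <- predictors[vapply(predictors, function(p)
    length(unique(design[[p]])) > 1L, logical(1))]
  dropped <- setdiff(predictors, keep)
  if (length(dropped))
    warning("dropping constant predictor(s): ", paste(dropped, collapse = ", "))
  form <- if (length(keep))
    stats::reformulate(keep, response = "converted") else converted ~ 1
  fit <- stats::glm(form, family = stats::binomial("logit"), data = design,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  sm <- summary(fit)
  co <- sm$coefficients
  separated <- any(abs(co[, "Estimate"]) > 15) || !fit$converged
  if (separated && !fit$converged)
    warning("IRLS did not converge (possible perfect separation)")
  tab <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], z = co[, "z value"],
                    p = co[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, glm = fit, converged = fit$converged,
                 n_iter = fit$iter, predictors = keep,
                 dropped_predictors = dropped),
            class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat("SNP conversion model (binomial, logit link)\n")
  cat("  n =", length(x$glm$y), " converged:", x$converged,
      " iterations:", x$n_iter, "\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  if (!is.null(tab$ci_low)) {
    tab$ci_low <- round(tab$ci_low, 3)
    tab$ci_high <- round(tab$ci_high, 3)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.conversion_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Parametric bootstrap confidence intervals on the log-odds scale
#'
#' Resamples responses from Bernoulli(fitted probability), refits, and
#' takes percentile bounds per coefficient.
#'
#' @param fit a [fit_logistic()] result.
#' @param design the design data.frame used for the fit.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return the fit with `ci_low`/`ci_high` columns added to
#'   `$coefficients`; errors if more than 1% of refits fail to converge.
#' @export
bootstrap_ci <- function(fit, design, B = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(fit, "conversion_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  p_hat <- stats::fitted(fit$glm)
  set.seed(seed)
  terms <- fit$coefficients$term
  draws <- matrix(NA_real_, B, length(terms))
  bad <- 0L
  d <- design
  for (b in seq_len(B)) {
    d$converted <- stats::rbinom(length(p_hat), 1L, p_hat)
    rf <- tryCatch(
      suppressWarnings(stats::glm(stats::formula(fit$glm),
                                  family = stats::binomial("logit"), data = d,
                                  control = stats::glm.control(epsilon = 1e-8,
                                                               maxit = 100))),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { bad <- bad + 1L; next }
    draws[b, ] <- stats::coef(rf)[terms]
  }
  if (bad > 0.01 * B)
    stop(bad, " of ", B, " bootstrap refits failed to converge")
  a <- (1 - conf) / 2
  fit$coefficients$ci_low <- apply(draws, 2, stats::quantile, probs = a,
                                   na.rm = TRUE)
  fit$coefficients$ci_high <- apply(draws, 2, stats::quantile, probs = 1 - a,
                                    na.rm = TRUE)
  fit$boot <- draws
  fit$n_boot <- B
  fit
}

#' Predicted conversion probability for a covariate combination
#'
#' Inverse logit of the linear predictor: p = 1 / (1 + exp(-(b0 + sum(b*x)))).
#'
#' @param fit a [fit_logistic()] result, or a named coefficient vector with
#'   an `(Intercept)` entry.
#' @param covariates named 0/1 vector; omitted terms default to 0.
#' @return probability in (0, 1).
#' @export
predict_probability <- function(fit, covariates = c()) {
  beta <- if (inherits(fit, "conversion_fit")) coef(fit) else fit
  eta <- unname(beta["(Intercept)"])
  if (is.na(eta)) eta <- 0
  slopes <- beta[setdiff(names(beta), "(Intercept)")]
  for (nm in names(covariates)) {
    if (!nm %in% names(slopes)) stop("unknown covariate: ", nm)
    eta <- eta + slopes[[nm]] * covariates[[nm]]
  }
  1 / (1 + exp(-eta))
}
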