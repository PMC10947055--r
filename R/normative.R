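#' Fit the demographic regression for one layer
#'
#' Ordinary least squares of per-participant mean layer thickness on age
#' (years), spherical equivalent (dioptres) and sex (indicator, female = 0,
#' male = 1), all as main effects.
#'
#' @param means numeric vector of mean layer thickness (um), one per
#'   participant.
#' @param covariates data.frame with columns `age`, `se` and `sex`
#'   ("M"/"F" or 0/1).
#' @param layer label stored with the model.
#' @return An object of class `normative_model`: `layer`, `terms`
#'   (data.frame covariate/estimate/se/p_value), `intercept`, `n`, `fit`
#'   (the underlying `lm`).
#' @export
fit_normative_model <- function(means, covariates, layer = "GCIPL") {
  stopifnot(is.numeric(means), nrow(covariates) == length(means),
            all(c("age", "se", "sex") %in% names(covariates)),
            length(means) >= 10)
  d <- data.frame(y = means, age = covariates$age, se = covariates$se,
                  sex = as.numeric(covariates$sex == "M" | covariates$sex == 1))
  if (any(vapply(d[c("age", "se", "sex")], function(v) stats::var(v) == 0,
                 logical(1))))
    stop("degenerate covariate (zero variance)")
  fit <- stats::lm(y ~ age + se + sex, data = d)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  cf <- summary(fit)$coefficients
  structure(list(
    layer = layer,
    terms = data.frame(covariate = rownames(cf)[-1],
                       estimate = cf[-1, 1], se = cf[-1, 2],
                       p_value = cf[-1, 4], row.names = NULL),
    intercept = cf[1, 1], n = length(means), fit = fit,
    data = d), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %s (n = %d)\n", x$layer, x$n))
  print(x$terms, digits = 4)
  invisible(x)
}

#' One round of backward stepwise elimination
#'
#' Removes the least significant main effect (largest p-value), refits, and
#' compares every retained coefficient before and after removal. If any
#' retained coefficient changes by at least `threshold_pct` percent of its
#' pre-removal magnitude, the removed effect contributed meaningfully and is
#' reinstated (final model keeps all covariates); otherwise the final model
#' drops it. A single elimination round is performed.
#'
#' @param model a [normative_model] with >= 2 covariates.
#' @param threshold_pct reinstatement threshold (percent, default 10).
#' @return An `elimination_report`: `removed_covariate`, `pct_changes`
#'   (named, percent, absolute value), `reinstated`, `final_covariates`,
#'   `refit_terms`.
#' @export
backward_stepwise_elimination <- function(model, threshold_pct = 10) {
  stopifnot(inherits(model, "normative_model"), nrow(model$terms) >= 2)
  drop_cov <- model$terms$covariate[which.max(model$terms$p_value)]
  keep <- setdiff(model$terms$covariate, drop_cov)
  refit <- stats::lm(stats::reformulate(keep, response = "y"),
                     data = model$data)
  cf <- summary(refit)$coefficients
  pre <- stats::setNames(model$terms$estimate, model$terms$covariate)[keep]
  post <- cf[keep, 1]
  pct <- ifelse(pre == 0, ifelse(post == pre, 0, Inf),
                abs(post - pre) / abs(pre) * 100)
  reinstated <- any(pct >= threshold_pct)
  structure(list(
    removed_covariate = drop_cov,
    pct_changes = pct,
    reinstated = reinstated,
    final_covariates = if (reinstated) model$terms$covariate else keep,
    refit_terms = data.frame(covariate = rownames(cf)[-1],
                             estimate = cf[-1, 1], se = cf[-1, 2],
                             row.names = NULL)),
    class = "elimination_report")
}

#' @export
print.elimination_report <- function(x, ...) {
  cat(sprintf("<elimination_report> removed %s; |change| %s; %s\n",
              x$removed_covariate,
              paste(sprintf("%s %.2f%%", names(x$pct_changes), x$pct_changes),
                    collapse = ", "),
              if (x$reinstated) "reinstated" else "excluded"))
  cat("  final covariates:", paste(x$final_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Covariates that must be matched when building deviation maps
#'
#' The final covariate set of the elimination report; downstream subgroup
#' matching uses exactly this set.
#'
#' @param report an `elimination_report`.
#' @return Character vector (subset of `c("age", "se", "sex")`).
#' @export
required_matching_covariates <- function(report) {
  stopifnot(inherits(report, "elimination_report"))
  report$final_covariates
}
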