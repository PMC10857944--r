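#' Build the per-station model table for one species
#'
#' Assembles the modelling frame of the detection-rate GLM: one row per
#' station with the species' contact count, the station's land-cover class
#' (factor with the chosen reference level first), its human detection rate,
#' and the log deployment duration used as the effort offset.
#'
#' @param contacts a `contact_table` from [filter_independent()].
#' @param dataset the source [survey_dataset()].
#' @param species canonical species label.
#' @param human_rates per-station rate table from [human_detection_rates()];
#'   computed from `contacts` when `NULL`. Every station must be present.
#' @param reference land-cover reference level (default `"clearfell"`).
#' @return Data frame `station_id,count,land_cover,human_rate,log_duration`.
#' @export
build_model_table <- function(contacts, dataset, species, human_rates = NULL,
                              reference = "clearfell") {
  stopifnot(inherits(contacts, "contact_table"), inherits(dataset, "survey_dataset"))
  species <- canonical_label(species)
  reference <- canonical_label(reference)
  if (!reference %in% land_cover_classes)
    stop_ctti("reference must be one of: ", paste(land_cover_classes, collapse = ", "))
  dep <- dataset$deployments
  if (is.null(human_rates)) human_rates <- human_detection_rates(contacts, dataset)
  missing_st <- setdiff(dep$station_id, human_rates$station_id)
  if (length(missing_st))
    stop_ctti("station(s) missing from human_rates: ", paste(missing_st, collapse = ", "))

  cs <- contacts[contacts$species == species, , drop = FALSE]
  n <- table(factor(cs$station_id, levels = dep$station_id))
  data.frame(
    station_id = dep$station_id,
    count = as.integer(n),
    land_cover = stats::relevel(factor(dep$land_cover, levels = land_cover_classes),
                                ref = reference),
    human_rate = human_rates$human_rate[match(dep$station_id, human_rates$station_id)],
    log_duration = log(dep$duration_days),
    stringsAsFactors = FALSE
  )
}

#' Fit a per-species detection-rate model
#'
#' Fits the negative binomial GLM (log link) of per-station contact counts on
#' land cover and human detection rate, with log deployment duration as an
#' offset so that coefficients are interpretable as log detection-rate
#' differences. The NB size parameter `theta` is estimated by maximum
#' likelihood ([MASS::glm.nb()]). Also reports Wald standard errors and
#' two-sided p-values, Nagelkerke pseudo-R-squared against the
#' intercept-plus-offset null, and per-coefficient separation flags: a design
#' cell with no contacts drives its log-scale coefficient towards minus
#' infinity with an inflated standard error, which is surfaced (flagged)
#' rather than regularized away.
#'
#' Model terms with no variation across stations (a single observed
#' land-cover level, or a constant human rate) are dropped from the formula
#' automatically, which covers intercept-only designs.
#'
#' @param contacts a `contact_table`.
#' @param dataset the source [survey_dataset()].
#' @param species canonical species label.
#' @param human_rates optional rate table (see [build_model_table()]).
#' @param reference land-cover reference level.
#' @param family `"nbinom"` (default) or `"poisson"` (used for the
#'   overdispersion diagnostic of [check_overdispersion()]).
#' @param se_threshold absolute standard-error threshold (log scale) above
#'   which a coefficient is separation-flagged (default 10).
#' @return An object of class `detection_model`: the underlying fit plus the
#'   coefficient table, `theta`, `pseudo_r2`, `separation` flags and the
#'   model table. Supports `print`, `summary`, `coef`, `vcov`, `confint`,
#'   `predict` and `residuals`.
#' @export
fit_detection_model <- function(contacts, dataset, species, human_rates = NULL,
                                reference = "clearfell",
                                family = c("nbinom", "poisson"),
                                se_threshold = 10) {
  family <- match.arg(family)
  tab <- build_model_table(contacts, dataset, species, human_rates, reference)
  tab$land_cover <- droplevels(tab$land_cover)
  if (any(tab$count < 0) || any(tab$count != round(tab$count)))
    stop_ctti("counts must be non-negative integers")

  terms <- character(0)
  if (nlevels(tab$land_cover) > 1) terms <- c(terms, "land_cover")
  if (stats::sd(tab$human_rate) > 0) terms <- c(terms, "human_rate")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("count ~", rhs, "+ offset(log_duration)"))
  null_form <- count ~ 1 + offset(log_duration)

  if (family == "nbinom") {
    fit <- withCallingHandlers(
      MASS::glm.nb(form, data = tab, maxit = 100,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    null_fit <- withCallingHandlers(
      MASS::glm.nb(null_form, data = tab, maxit = 100,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    theta <- fit$theta
  } else {
    fit <- stats::glm(form, data = tab, family = stats::poisson())
    null_fit <- stats::glm(null_form, data = tab, family = stats::poisson())
    theta <- NULL
  }
  if (!fit$converged)
    stop_ctti("detection-rate model did not converge for ", species)

  sm <- stats::coef(summary(fit))
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    z_value = sm[, 3],
    p_value = sm[, 4],
    rate_ratio = exp(sm[, 1]),
    separation = abs(sm[, 2]) > se_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    species = species,
    family = family,
    fit = fit,
    null_fit = null_fit,
    coefficients = coefs,
    theta = theta,
    pseudo_r2 = nagelkerke_r2(fit, null_fit, n = nrow(tab)),
    loglik = as.numeric(stats::logLik(fit)),
    separation = stats::setNames(coefs$separation, coefs$term),
    se_threshold = se_threshold,
    reference = reference,
    table = tab,
    formula = form
  ), class = "detection_model")
}

# Nagelkerke (Cragg-Uhler) pseudo-R2 against the intercept+offset null
nagelkerke_r2 <- function(fit, null_fit, n) {
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  cox_snell <- 1 - exp((ll0 - ll1) * 2 / n)
  max_r2 <- 1 - exp(ll0 * 2 / n)
  if (max_r2 <= 0) return(0)
  min(max(cox_snell / max_r2, 0), 1)
}

#' Pearson overdispersion diagnostic for a count model
#'
#' Computes the Pearson dispersion ratio (sum of squared Pearson residuals
#' over residual degrees of freedom) of a fitted count GLM — typically the
#' Poisson fit of the detection-rate formula — and declares overdispersion
#' when the ratio exceeds a threshold. A ratio near 1 is consistent with
#' equidispersion; substantially more motivates the negative binomial.
#'
#' @param fit a fitted `glm` (e.g. Poisson), or a `detection_model`.
#' @param threshold dispersion-ratio threshold for the verdict (default 1.4).
#' @return List with `ratio`, `overdispersed` (logical verdict),
#'   `threshold`, `df_residual`.
#' @export
check_overdispersion <- function(fit, threshold = 1.4) {
  if (inherits(fit, "detection_model")) fit <- fit$fit
  stopifnot(inherits(fit, "glm"))
  df <- stats::df.residual(fit)
  if (df <= 0) stop_ctti("no residual degrees of freedom")
  ratio <- sum(stats::residuals(fit, type = "pearson")^2) / df
  list(ratio = ratio, overdispersed = ratio > threshold,
       threshold = threshold, df_residual = df)
}

#' Convert a log-scale coefficient to a rate ratio
#'
#' `exp(estimate)`: the multiplicative (fold) change in detection rate
#' associated with the coefficient, e.g. of a land-cover level relative to
#' the reference level.
#'
#' @param estimate log-scale coefficient(s).
#' @return `exp(estimate)`.
#' @export
rate_ratio <- function(estimate) {
  stopifnot(is.numeric(estimate), all(is.finite(estimate)))
  exp(estimate)
}

#' @export
coef.detection_model <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.detection_model <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.detection_model <- function(object, parm, level = 0.95, ...) {
  # Wald intervals on the log scale (profile likelihood is unstable under
  # separation, which this model class deliberately surfaces)
  b <- stats::coef(object$fit)
  se <- sqrt(diag(stats::vcov(object$fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.detection_model <- function(object, newdata = NULL,
                                    type = c("link", "response"), ...) {
  type <- match.arg(type)
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.detection_model <- function(object, type = "pearson", ...) {
  stats::residuals(object$fit, type = type, ...)
}

#' @export
print.detection_model <- function(x, digits = 3, ...) {
  cat(sprintf("Detection-rate model (%s GLM, log link, log-effort offset): %s\n",
              if (x$family == "nbinom") "negative binomial" else "Poisson",
              x$species))
  cat(sprintf("  reference land cover: %s; stations: %d\n",
              x$reference, nrow(x$table)))
  if (!is.null(x$theta))
    cat(sprintf("  theta = %.3g; Nagelkerke R2 = %.2f\n", x$theta, x$pseudo_r2))
  else
    cat(sprintf("  Nagelkerke R2 = %.2f\n", x$pseudo_r2))
  ct <- x$coefficients
  ct$estimate <- round(ct$estimate, digits)
  ct$std_error <- round(ct$std_error, digits)
  ct$rate_ratio <- round(ct$rate_ratio, 2)
  ct$p_value <- signif(ct$p_value, 2)
  ct$z_value <- NULL
  print.data.frame(ct, row.names = FALSE)
  if (any(x$separation))
    cat("  note: flagged coefficients (separation = TRUE) come from design cells\n",
        "  with no contacts; their estimates and SEs are unreliable.\n", sep = "")
  invisible(x)
}

#' @export
summary.detection_model <- function(object, ...) {
  out <- list(model = object, dispersion = tryCatch(
    check_overdispersion(object), error = function(e) NULL))
  class(out) <- "summary.detection_model"
  out
}

#' @export
print.summary.detection_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$dispersion))
    cat(sprintf("Pearson dispersion ratio: %.2f (%soverdispersed at threshold %.2f)\n",
                x$dispersion$ratio,
                if (x$dispersion$overdispersed) "" else "not ",
                x$dispersion$threshold))
  invisible(x)
}
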