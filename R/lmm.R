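#' Random-intercept linear mixed model
#'
#' Fits `response ~ fixed + (1 | group)` by full maximum likelihood
#' (not REML), so that likelihood-ratio tests on the fixed effects are
#' valid and BIC values are comparable across nested models. Wald 95%
#' confidence intervals are reported for every fixed effect. A singular
#' fit (random-intercept variance estimated at zero) is flagged, not an
#' error: the fixed effects then coincide with pooled ordinary least
#' squares.
#'
#' @param data A data frame of trials.
#' @param response Response column name (string).
#' @param fixed Right-hand side of the fixed part as a string, e.g.
#'   `"ttc"` or `"ttc * gs_rel"`; `NULL` fits an intercept-only model.
#' @param group Grouping column for the random intercept (default
#'   `"participant_id"`).
#' @return An object of class `ttc_lmm`: a list with the fitted `lme4`
#'   model, a `fixed` tibble (term, estimate, se, t, conf_low, conf_high),
#'   `participant_sd`, `sigma`, `log_lik`, `bic`, `nobs`, `n_fixed`,
#'   `singular` and the formula label. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' trials <- generate_dataset(simulation_config(n_participants = 3,
#'                                              n_early = 2, blocks = 1),
#'                            seed = 7)
#' trials$ttc <- as.numeric(trials$flight_time > 3)
#' fit_random_intercept_lmm(trials, "response_time", "ttc")
#' @export
fit_random_intercept_lmm <- function(data, response, fixed = NULL,
                                     group = "participant_id") {
  if (length(unique(data[[group]])) < 2) {
    abort("at least 2 grouping levels are required",
          class = "parattc_validation_error")
  }
  rhs <- if (is.null(fixed) || !nzchar(fixed)) "1" else fixed
  label <- paste0(response, " ~ ", rhs, " + (1 | ", group, ")")
  model <- suppressMessages(lme4::lmer(
    as.formula(label), data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  singular <- lme4::isSingular(model)
  cf <- coef(summary(model))
  se <- cf[, "Std. Error"]
  est <- cf[, "Estimate"]
  z <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(model))
  part_sd <- vc$sdcor[vc$grp == group][1]
  structure(
    list(
      model = model,
      label = label,
      response = response,
      fixed_rhs = rhs,
      fixed = tibble::tibble(
        term = rownames(cf),
        estimate = unname(est),
        se = unname(se),
        t = unname(cf[, "t value"]),
        conf_low = unname(est - z * se),
        conf_high = unname(est + z * se)
      ),
      participant_sd = max(part_sd, 0),
      sigma = stats::sigma(model),
      log_lik = as.numeric(logLik(model)),
      bic = BIC(model),
      nobs = stats::nobs(model),
      n_fixed = nrow(cf),
      singular = singular
    ),
    class = "ttc_lmm"
  )
}

#' @export
print.ttc_lmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat("  ", x$label, "\n", sep = "")
  cat(sprintf("  nobs = %d, logLik = %.2f, BIC = %.1f%s\n",
              x$nobs, x$log_lik, x$bic,
              if (x$singular) " (singular: zero intercept variance)" else ""))
  print(x$fixed)
  invisible(x)
}

#' Tidy a random-intercept mixed-model fit
#'
#' @param x A `ttc_lmm` object.
#' @param ... Unused.
#' @return `tidy()`: one row per fixed effect with estimate, standard
#'   error, t statistic and Wald 95% CI. `glance()`: one-row model
#'   summary (log-likelihood, BIC, residual and intercept SDs, nobs).
#' @method tidy ttc_lmm
#' @export
tidy.ttc_lmm <- function(x, ...) {
  x$fixed
}

#' @rdname tidy.ttc_lmm
#' @method glance ttc_lmm
#' @export
glance.ttc_lmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik,
    BIC = x$bic,
    sigma = x$sigma,
    participant_sd = x$participant_sd,
    nobs = x$nobs,
    n_fixed = x$n_fixed,
    singular = x$singular
  )
}

#' Likelihood-ratio test between nested mixed models
#'
#' Twice the log-likelihood difference between a test model and a null
#' model nested within it (both fitted by ML on the same data), referred
#' to a chi-square distribution with degrees of freedom equal to the
#' difference in fixed-effect count.
#'
#' @param null,test `ttc_lmm` fits; `null` must be nested in `test`.
#' @return A one-row tibble of class `ttc_lrt` with `chi_square`, `df`,
#'   `p_value`, `bic_null`, `bic_test`.
#' @export
likelihood_ratio_test <- function(null, test) {
  if (!inherits(null, "ttc_lmm") || !inherits(test, "ttc_lmm")) {
    abort("both arguments must be ttc_lmm fits",
          class = "parattc_validation_error")
  }
  if (null$response != test$response || null$nobs != test$nobs) {
    abort("models must be fitted to the same response and data",
          class = "parattc_validation_error")
  }
  if (!all(null$fixed$term %in% test$fixed$term) ||
      null$n_fixed > test$n_fixed) {
    abort("null model is not nested in the test model",
          class = "parattc_validation_error")
  }
  chi <- max(0, 2 * (test$log_lik - null$log_lik))
  df <- test$n_fixed - null$n_fixed
  out <- tibble::tibble(
    chi_square = chi,
    df = df,
    p_value = if (df == 0) 1 else pchisq(chi, df, lower.tail = FALSE),
    bic_null = null$bic,
    bic_test = test$bic
  )
  class(out) <- c("ttc_lrt", class(out))
  out
}
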