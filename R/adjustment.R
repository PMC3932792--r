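# Covariate-adjusted genotype effect on the MetS score via ordinary least
# squares, with a marginal incremental R-squared screening rule for which
# covariates enter the model.

#' Screen covariates by marginal contribution to score variance
#'
#' The contribution of each candidate covariate is its incremental R-squared
#' when added alone to an intercept-only model of the score (the marginal
#' reading of "share of score variation explained"); covariates contributing
#' more than `threshold` are retained.  A partial-eta-squared alternative
#' (each covariate's partial contribution in the joint model) is available
#' via `metric = "partial"`.
#'
#' @param data Data frame holding the score and the covariates.
#' @param score Name of the score column (default `"score"`).
#' @param covariates Character vector of covariate column names; logicals
#'   are coded 0/1 and `sex` is coded female = 1.
#' @param threshold Inclusion threshold on the contribution (default 0.05).
#' @param metric `"marginal"` (default) or `"partial"`.
#' @return Tibble: `covariate`, `contribution`, `included`, `note`
#'   (constant covariates get contribution 0 and are excluded).
#' @export
covariate_screen <- function(data, score = "score", covariates,
                             threshold = 0.05,
                             metric = c("marginal", "partial")) {
  metric <- match.arg(metric)
  df <- encode_covariates(data, c(score, covariates))
  y <- df[[score]]
  if (metric == "partial") {
    full <- lm(stats::reformulate(covariates, response = score), data = df)
    a <- stats::drop1(full, test = "F")
    ss_res <- sum(stats::residuals(full)^2)
    contrib <- setNames(a$`Sum of Sq`[-1] /
                          (a$`Sum of Sq`[-1] + ss_res), rownames(a)[-1])
  }
  purrr::map_dfr(covariates, function(cv) {
    x <- df[[cv]]
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      return(tibble::tibble(covariate = cv, contribution = 0,
                            included = FALSE, note = "constant"))
    }
    contribution <- if (metric == "marginal") {
      # marginal incremental R^2 of a single regressor is its squared
      # correlation with the outcome
      cor(y, x, use = "complete.obs")^2
    } else {
      unname(contrib[cv])
    }
    tibble::tibble(covariate = cv, contribution = contribution,
                   included = contribution > threshold, note = "")
  })
}

encode_covariates <- function(data, cols) {
  out <- tibble::as_tibble(data)[cols]
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.numeric(out[[nm]])
    if (nm == "sex" || is.character(out[[nm]]) || is.factor(out[[nm]])) {
      lv <- sort(unique(as.character(out[[nm]])))
      if (length(lv) > 2) {
        abort(paste0("Covariate '", nm, "' has more than two levels; ",
                     "recode it numerically."),
              class = "metscore_parameter_error")
      }
      ref <- if (nm == "sex" && "male" %in% lv) "male" else lv[1]
      out[[nm]] <- as.numeric(as.character(out[[nm]]) != ref)
    }
  }
  out
}

#' Covariate-adjusted genotype-group difference in the MetS score
#'
#' Least-squares fit of `score ~ carrier + covariates` with treatment
#' coding.  The adjusted difference is reported as reference minus carrier
#' (the same orientation as the unadjusted association tables), with CI and
#' p-value from the coefficient's t distribution on the residual degrees of
#' freedom.  With no covariates this reduces exactly to the pooled
#' two-sample t-test.
#'
#' @param data Data frame holding score, grouping and covariates.
#' @param score Name of the score column.
#' @param group Name of the logical/0-1 carrier indicator column.
#' @param covariates Character vector of covariate columns (possibly empty),
#'   e.g. the `included` set from [covariate_screen()].
#' @param level Confidence level (default 0.95).
#' @return Tibble of class `adjusted_fit` (one row): `estimate`
#'   (reference - carrier), `conf_low`, `conf_high`, `statistic`, `df`,
#'   `p_value`, `n`, `covariates` (list column).  The underlying `lm` fit is
#'   attached as attribute `"fit"`.
#' @export
fit_adjusted_model <- function(data, score = "score", group = "carrier",
                               covariates = character(), level = 0.95) {
  df <- encode_covariates(data, c(score, group, covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df[[group]])) < 2 || min(table(df[[group]])) < 2) {
    abort("Need at least 2 individuals in each genotype group.",
          class = "metscore_insufficient_data")
  }
  form <- stats::reformulate(c(group, covariates), response = score)
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0("Collinear design; aliased column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "metscore_rank_deficient")
  }
  est_carrier <- coef(fit)[[group]]
  se <- sqrt(diag(vcov(fit)))[[group]]
  df_res <- fit$df.residual
  stat <- est_carrier / se
  tcrit <- qt((1 + level) / 2, df_res)
  # flip sign: report reference-minus-carrier like the unadjusted tables
  out <- tibble::tibble(
    estimate = -est_carrier,
    conf_low = -est_carrier - tcrit * se,
    conf_high = -est_carrier + tcrit * se,
    statistic = -stat, df = df_res,
    p_value = 2 * pt(-abs(stat), df_res),
    n = nrow(df), covariates = list(covariates), level = level)
  class(out) <- c("adjusted_fit", class(out))
  attr(out, "fit") <- fit
  out
}

#' @export
tidy.adjusted_fit <- function(x, ...) {
  f <- attr(x, "fit")
  s <- summary(f)$coefficients
  ci <- confint(f)
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4],
                 conf_low = ci[, 1], conf_high = ci[, 2])
}

#' @export
glance.adjusted_fit <- function(x, ...) {
  f <- attr(x, "fit")
  s <- summary(f)
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, df_residual = f$df.residual, n = x$n)
}

#' Adjusted association of every SNP with the score
#'
#' Runs [covariate_screen()] once on the cohort, then
#' [fit_adjusted_model()] per SNP under the dominance grouping.  The
#' genotype term is always retained; screening applies to covariates only.
#'
#' @param scores Data frame with `id` and `score`.
#' @param genotypes Data frame with `id` and one dosage column per SNP.
#' @param phenotypes Data frame with `id` and candidate covariate columns.
#' @param covariates Candidate covariate names (default: age, sex and the
#'   four lifestyle factors).
#' @param threshold Screening threshold (default 0.05).
#' @return List with `screen` (the screening report) and `results` (tibble,
#'   one row per SNP; degenerate SNPs are skipped with a note).
#' @export
associate_snps_adjusted <- function(scores, genotypes, phenotypes,
                                    covariates = c("age_years", "sex", "smoker",
                                                   "excess_alcohol", "inactive",
                                                   "unhealthy_diet"),
                                    threshold = 0.05) {
  merged <- tibble::as_tibble(scores) |>
    dplyr::inner_join(tibble::as_tibble(phenotypes), by = "id") |>
    dplyr::inner_join(tibble::as_tibble(genotypes), by = "id")
  screen <- covariate_screen(merged, score = "score", covariates = covariates,
                             threshold = threshold)
  keep <- screen$covariate[screen$included]
  snps <- setdiff(names(genotypes), "id")
  results <- purrr::map_dfr(snps, function(s) {
    dat <- dplyr::mutate(merged, carrier = .data[[s]] >= 1)
    res <- tryCatch(
      fit_adjusted_model(dat, score = "score", group = "carrier",
                         covariates = keep),
      error = function(e) tibble::tibble(estimate = NA_real_,
                                         p_value = NA_real_))
    note <- if (is.na(res$estimate[1])) "skipped" else ""
    tibble::add_column(tibble::as_tibble(res)[
      intersect(c("estimate", "conf_low", "conf_high", "statistic", "df",
                  "p_value", "n"), names(res))],
      snp_id = s, .before = 1) |>
      dplyr::mutate(note = note)
  })
  list(screen = screen, results = results)
}
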