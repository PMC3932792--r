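# Harmonized dichotomous MetS classification: five feature flags with
# sex-specific cut-offs and medication overrides, risk-factor counts, and
# prevalence with a normal-approximation confidence interval.

#' Harmonized MetS criteria thresholds
#'
#' Cut-offs of the harmonized definition: elevated waist circumference
#' (men >= 94 cm, women >= 80 cm), low HDL (men < 40, women < 50 mg/dL),
#' elevated triglycerides (>= 150 mg/dL), elevated blood pressure
#' (SBP >= 130 or DBP >= 85 mmHg), elevated glucose (>= 100 mg/dL).
#' Medication counts as an alternative indicator for its feature;
#' lipid-lowering medication maps to both lipid features by default
#' (configurable via `med_chol_features`).
#'
#' @param waist_male,waist_female,hdl_male,hdl_female,tg,sbp,dbp,glucose
#'   Numeric cut-offs.
#' @param med_chol_features Which lipid features `med_chol` overrides
#'   (subset of `c("low_hdl", "high_tg")`).
#' @return List of class `mets_thresholds`.
#' @export
mets_thresholds <- function(waist_male = 94, waist_female = 80,
                            hdl_male = 40, hdl_female = 50,
                            tg = 150, sbp = 130, dbp = 85, glucose = 100,
                            med_chol_features = c("low_hdl", "high_tg")) {
  th <- list(waist_male = waist_male, waist_female = waist_female,
             hdl_male = hdl_male, hdl_female = hdl_female,
             tg = tg, sbp = sbp, dbp = dbp, glucose = glucose,
             med_chol_features = match.arg(med_chol_features,
                                           c("low_hdl", "high_tg"),
                                           several.ok = TRUE))
  if (any(vapply(th[1:8], function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    abort("All thresholds must be positive numbers.",
          class = "metscore_parameter_error")
  }
  structure(th, class = "mets_thresholds")
}

#' Classify MetS status from a phenotype table
#'
#' Evaluates the five harmonized features per participant.  A feature is
#' present iff its threshold is met or the corresponding medication flag is
#' set; waist, TG, BP and glucose cut-offs are inclusive (`>=`), the HDL
#' cut-off is strict (`<`).  A missing trait whose feature has no medication
#' override leaves that feature (and the totals) missing; affected records
#' are reported in a warning.
#'
#' @param data Phenotype data frame with trait columns, `sex`
#'   (`"male"`/`"female"`), and logical `med_htn`, `med_chol`, `med_diab`.
#' @param thresholds A [mets_thresholds()] object.
#' @return Tibble: `id` (if present), five logical feature columns
#'   (`abdominal_obesity`, `low_hdl`, `high_tg`, `elevated_bp`,
#'   `hyperglycemia`), `risk_count` (0-5) and `mets` (`risk_count >= 3`).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 100, seed = 1))
#' status <- classify_mets(cohort$phenotypes)
#' table(status$risk_count)
classify_mets <- function(data, thresholds = mets_thresholds()) {
  if (!inherits(thresholds, "mets_thresholds")) {
    abort("`thresholds` must come from mets_thresholds().",
          class = "metscore_parameter_error")
  }
  need <- c(mets_traits(), "sex", "med_htn", "med_chol", "med_diab")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "metscore_schema_error")
  }
  female <- data$sex == "female"
  med <- function(x) !is.na(x) & x  # missing medication flag treated as FALSE

  waist_cut <- ifelse(female, thresholds$waist_female, thresholds$waist_male)
  hdl_cut <- ifelse(female, thresholds$hdl_female, thresholds$hdl_male)
  med_hdl <- if ("low_hdl" %in% thresholds$med_chol_features) med(data$med_chol) else FALSE
  med_tg <- if ("high_tg" %in% thresholds$med_chol_features) med(data$med_chol) else FALSE

  feat <- tibble::tibble(
    abdominal_obesity = data$waist_cm >= waist_cut,
    low_hdl = (data$hdl_mg_dl < hdl_cut) | med_hdl,
    high_tg = (data$tg_mg_dl >= thresholds$tg) | med_tg,
    elevated_bp = (data$sbp_mmHg >= thresholds$sbp) |
      (data$dbp_mmHg >= thresholds$dbp) | med(data$med_htn),
    hyperglycemia = (data$glucose_mg_dl >= thresholds$glucose) | med(data$med_diab)
  )
  # medication TRUE forces the feature even when the measurement is missing;
  # NA | TRUE is already TRUE in R, so only NA-with-FALSE-override remains NA
  out <- feat |>
    dplyr::mutate(risk_count = rowSums(dplyr::pick(dplyr::everything())),
                  mets = .data$risk_count >= 3)
  if (!is.null(data[["id"]])) out <- tibble::add_column(out, id = data[["id"]], .before = 1)
  incomplete <- which(is.na(out$risk_count))
  if (length(incomplete) > 0) {
    labs <- if (!is.null(data[["id"]])) data$id[incomplete] else incomplete
    warn(paste0("Missing feature(s) without medication override for record(s): ",
                paste(utils::head(labs, 10L), collapse = ", "),
                if (length(labs) > 10) " ..."))
  }
  out
}

#' Confidence interval for a prevalence estimate
#'
#' Wald normal-approximation interval
#' `p +/- z * sqrt(p (1 - p) / n)` truncated to `[0, 1]` (default), or the
#' Wilson score interval.
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Sample size (>= 1).
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return One-row tibble: `p_hat`, `n`, `conf_low`, `conf_high`, `method`.
#' @export
#' @examples
#' prevalence_ci(95 / 206, 206) # 46.12% (39.31-52.92%)
prevalence_ci <- function(p_hat, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (p_hat < 0 || p_hat > 1 || n < 1) {
    abort("Need 0 <= p_hat <= 1 and n >= 1.", class = "metscore_parameter_error")
  }
  z <- qnorm((1 + level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p_hat * (1 - p_hat) / n)
    lo <- max(0, p_hat - half)
    hi <- min(1, p_hat + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p_hat + z^2 / (2 * n)) / den
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / den
    lo <- ctr - half
    hi <- ctr + half
  }
  tibble::tibble(p_hat = p_hat, n = n, conf_low = lo, conf_high = hi,
                 level = level, method = method)
}

#' MetS prevalence summary from a classification table
#'
#' @param status Output of [classify_mets()] (records with missing `mets`
#'   are excluded).
#' @inheritParams prevalence_ci
#' @return One-row tibble: `n`, `n_mets`, `p_hat`, `conf_low`, `conf_high`.
#' @export
mets_prevalence <- function(status, level = 0.95, method = "wald") {
  m <- status$mets[!is.na(status$mets)]
  n <- length(m)
  if (n == 0) abort("No classified records.", class = "metscore_insufficient_data")
  ci <- prevalence_ci(mean(m), n, level = level, method = method)
  tibble::tibble(n = n, n_mets = sum(m), p_hat = ci$p_hat,
                 conf_low = ci$conf_low, conf_high = ci$conf_high)
}

#' @export
autoplot.mets_thresholds <- function(object, ...) {
  tibble::tibble(
    feature = c("waist (M)", "waist (F)", "HDL (M)", "HDL (F)", "TG",
                "SBP", "DBP", "glucose"),
    cutoff = c(object$waist_male, object$waist_female, object$hdl_male,
               object$hdl_female, object$tg, object$sbp, object$dbp,
               object$glucose)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cutoff, y = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cut-off", y = NULL, title = "Harmonized MetS thresholds")
}
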