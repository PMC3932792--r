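# Normality screening, trait-specific normalizing transforms, and
# standardization of the six MetS risk factors ahead of PCA.

#' Default transform assignment for the six MetS traits
#'
#' SBP and TG receive a doubled decimal log, glucose a reciprocal tenth power
#' of its decimal log, HDL a squared natural log; waist circumference and DBP
#' are left untransformed.
#'
#' @return Named character vector mapping trait column to transform id
#'   (`"identity"`, `"log10log10"`, `"inv_log10_pow10"` or `"sq_ln"`).
#' @export
default_transforms <- function() {
  c(waist_cm = "identity",
    dbp_mmHg = "identity",
    sbp_mmHg = "log10log10",
    glucose_mg_dl = "inv_log10_pow10",
    hdl_mg_dl = "sq_ln",
    tg_mg_dl = "log10log10")
}

transform_ids <- function() c("identity", "log10log10", "inv_log10_pow10", "sq_ln")

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] that drops missing values and
#' returns a one-row tibble.  `shapiro.test()` accepts at most 5000
#' observations; larger vectors are deterministically thinned to 5000
#' evenly spaced order positions, which preserves the empirical distribution.
#'
#' @param values Numeric vector, at least 3 non-missing values.
#' @return Tibble with columns `n`, `statistic` (W) and `p_value`.
#' @export
shapiro_normality <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) {
    abort("shapiro_normality() needs at least 3 non-missing values.",
          class = "metscore_insufficient_data")
  }
  if (sd(x) == 0) {
    abort("shapiro_normality(): all values identical; W is undefined.",
          class = "metscore_degenerate_input")
  }
  if (length(x) > 5000) {
    idx <- round(seq(1, length(x), length.out = 5000))
    x <- sort(x)[idx]
  }
  sw <- shapiro.test(x)
  tibble::tibble(n = length(x),
                 statistic = unname(sw$statistic),
                 p_value = sw$p.value)
}

#' Apply a normalizing transform to trait values
#'
#' @param values Strictly positive numeric vector (missing values propagate).
#' @param transform One of `"identity"`, `"log10log10"` (log10 of log10),
#'   `"inv_log10_pow10"` (reciprocal tenth power of log10), `"sq_ln"`
#'   (squared natural log).
#' @param ids Optional record identifiers used in domain-error messages.
#' @return Numeric vector of transformed values.
#' @details The doubled-log transforms require values strictly greater than 1
#'   so that the inner log10 is positive; `sq_ln` requires values greater
#'   than 0 (and is monotone increasing only above 1).  Violations raise a
#'   domain error listing the offending records.
#' @export
#' @examples
#' transform_trait(100, "inv_log10_pow10") # 1 / 2^10
#' transform_trait(exp(1), "sq_ln")        # 1
transform_trait <- function(values, transform, ids = NULL) {
  transform <- match.arg(transform, transform_ids())
  ids <- ids %||% seq_along(values)
  ok <- !is.na(values)
  bad <- switch(transform,
    identity = ok & values <= 0,
    sq_ln = ok & values <= 0,
    log10log10 = ,
    inv_log10_pow10 = ok & values <= 1
  )
  if (any(bad)) {
    lim <- if (transform %in% c("log10log10", "inv_log10_pow10")) "> 1" else "> 0"
    abort(
      paste0("transform_trait('", transform, "') requires values ", lim,
             "; violated by record(s): ",
             paste(utils::head(ids[bad], 10L), collapse = ", ")),
      class = "metscore_domain_error")
  }
  switch(transform,
    identity = values,
    log10log10 = log10(log10(values)),
    inv_log10_pow10 = 1 / log10(values)^10,
    sq_ln = log(values)^2
  )
}

#' Invert a normalizing transform
#'
#' Inverse of [transform_trait()] on the valid domain; `sq_ln` takes the
#' increasing branch (values above 1).  `inv_log10_pow10` requires transformed
#' values strictly positive.
#'
#' @inheritParams transform_trait
#' @return Numeric vector on the raw trait scale.
#' @export
inverse_transform_trait <- function(values, transform) {
  transform <- match.arg(transform, transform_ids())
  ok <- !is.na(values)
  bad <- switch(transform,
    identity = rep(FALSE, length(values)),
    log10log10 = rep(FALSE, length(values)),
    inv_log10_pow10 = ok & values <= 0,
    sq_ln = ok & values < 0
  )
  if (any(bad)) {
    abort(paste0("inverse_transform_trait('", transform,
                 "'): value outside the invertible range."),
          class = "metscore_domain_error")
  }
  switch(transform,
    identity = values,
    log10log10 = 10^(10^values),
    inv_log10_pow10 = 10^((1 / values)^(1 / 10)),
    sq_ln = exp(sqrt(values))
  )
}

#' Build the per-trait transform specification
#'
#' In `"fixed"` mode (the default) the four designated transforms are applied
#' unconditionally and waist/DBP stay untransformed, which makes the score
#' construction reproducible on any cohort.  In `"screen"` mode each trait is
#' Shapiro-Wilk tested and receives its designated transform only when
#' normality is rejected at `alpha`; a trait that fails the screen but has no
#' designated non-identity transform errors in strict mode or is left
#' untransformed with a warning in lenient mode.
#'
#' @param data Data frame containing the six trait columns of [mets_traits()].
#' @param mode `"fixed"` or `"screen"`.
#' @param alpha Significance level for the screen (default 0.05).
#' @param strict In screen mode, error (TRUE) or warn (FALSE) when a
#'   non-normal trait has no designated transform.
#' @return Tibble of class `transform_spec` with columns `trait`,
#'   `statistic`, `p_value` (Shapiro-Wilk, on the raw values), `transform`,
#'   and post-transform `mean` and `sd` used downstream for standardization.
#' @export
build_transform_spec <- function(data, mode = c("fixed", "screen"),
                                 alpha = 0.05, strict = TRUE) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(mets_traits(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing trait column(s): ", paste(missing_cols, collapse = ", ")),
          class = "metscore_schema_error")
  }
  designated <- default_transforms()
  spec <- purrr::map_dfr(mets_traits(), function(tr) {
    sw <- shapiro_normality(data[[tr]])
    use <- designated[[tr]]
    if (mode == "screen") {
      if (sw$p_value >= alpha) {
        use <- "identity"
      } else if (designated[[tr]] == "identity") {
        msg <- paste0("Trait '", tr, "' fails the normality screen but has no ",
                      "designated transform.")
        if (strict) abort(msg, class = "metscore_screen_error")
        warn(paste(msg, "Left untransformed."))
        use <- "identity"
      }
    }
    tv <- transform_trait(data[[tr]], use, ids = data[["id"]])
    tibble::tibble(trait = tr, statistic = sw$statistic, p_value = sw$p_value,
                   transform = use,
                   mean = mean(tv, na.rm = TRUE), sd = sd(tv, na.rm = TRUE))
  })
  class(spec) <- c("transform_spec", class(spec))
  spec
}

#' Apply a transform specification to a cohort table
#'
#' @param data Data frame with the six trait columns; missing values propagate.
#' @param spec A `transform_spec` from [build_transform_spec()].
#' @return Tibble with the trait columns replaced by their transformed values
#'   (other columns untouched).
#' @export
apply_transforms <- function(data, spec) {
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(spec))) {
    tr <- spec$trait[i]
    out[[tr]] <- transform_trait(out[[tr]], spec$transform[i], ids = out[["id"]])
  }
  out
}

#' Standardize a trait matrix to zero mean and unit SD
#'
#' @param x Numeric matrix or data frame of transformed traits (columns).
#' @param center,scale Optional fixed constants (e.g. from a fitted model);
#'   defaults are the column means and SDs of `x`.
#' @return List with `z` (matrix), `center` and `scale` (named vectors).
#' @export
standardize_traits <- function(x, center = NULL, scale = NULL) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("standardize_traits() needs numeric columns.")
  center <- center %||% colMeans(m, na.rm = TRUE)
  scale <- scale %||% apply(m, 2, sd, na.rm = TRUE)
  if (any(scale <= 0 | !is.finite(scale))) {
    abort(paste0("Zero-variance column(s): ",
                 paste(colnames(m)[scale <= 0 | !is.finite(scale)], collapse = ", ")),
          class = "metscore_degenerate_input")
  }
  z <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  list(z = z, center = center, scale = scale)
}

# Serialize / read back a transform spec as a plain key-value text block.

#' Write or read a transform specification as plain text
#'
#' @param spec A `transform_spec`.
#' @param path File path.
#' @return `write_transform_spec()` returns `path` invisibly;
#'   `read_transform_spec()` returns the `transform_spec` tibble.
#' @export
write_transform_spec <- function(spec, path) {
  readr::write_tsv(tibble::as_tibble(spec), path)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  spec <- readr::read_tsv(path, show_col_types = FALSE)
  class(spec) <- c("transform_spec", class(spec))
  spec
}
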