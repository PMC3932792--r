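# PCA-based continuous MetS score: model fit on standardized transformed
# traits, varimax rotation of the retained components, component scores by
# the regression method (rotated with the same orthogonal matrix, so they
# stay exactly uncorrelated with unit sample variance), and the weighted sum
# that defines the score.

#' Fit the principal-component score model on a standardized trait matrix
#'
#' Eigendecomposes the correlation matrix of the (already standardized)
#' trait matrix, retains components with eigenvalue strictly above
#' `eigen_threshold`, optionally varimax-rotates the retained loadings
#' (Kaiser-normalized, the conventional default), recomputes explained
#' variance proportions after rotation, reorders components by decreasing
#' explained variance and orients each so its largest-magnitude loading is
#' positive.
#'
#' @param zmatrix Numeric matrix with one column per trait, columns
#'   standardized to mean 0 / SD 1 (see [standardize_traits()]); rows with
#'   missing values are dropped listwise.
#' @param eigen_threshold Retain components with eigenvalue strictly greater
#'   than this (default 1.0, the Kaiser rule).
#' @param rotate Apply varimax to the retained components (default TRUE;
#'   ignored when only one component is retained).
#' @param orientation PCA signs are arbitrary; `"adverse"` (default) orients
#'   each component so it correlates positively with the metabolically
#'   adverse direction of the traits (per `adverse_signs`), making a higher
#'   score a less favorable profile; `"max_loading"` makes each component's
#'   largest-magnitude loading positive (a content-agnostic convention).
#'   `"adverse"` falls back to `"max_loading"` when the columns are not the
#'   six canonical traits.
#' @param adverse_signs Named vector of +1/-1 giving the adverse direction
#'   of each trait on its transformed scale (glucose and HDL are negative
#'   because the glucose transform is decreasing and high HDL is
#'   protective).
#' @return Object of class `score_model`: a list with `loadings` (traits x K
#'   correlations between traits and components), `eigenvalues` (all
#'   components), `explained` (retained proportions of total variance,
#'   post-rotation), `k`, `rotation`, `score_coef` (traits x K matrix such
#'   that `z %*% score_coef` gives unit-variance component scores), `n`, and
#'   the trait names.
#' @export
fit_score_model <- function(zmatrix, eigen_threshold = 1.0, rotate = TRUE,
                            orientation = c("adverse", "max_loading"),
                            adverse_signs = c(waist_cm = 1, dbp_mmHg = 1,
                                              sbp_mmHg = 1, glucose_mg_dl = -1,
                                              hdl_mg_dl = -1, tg_mg_dl = 1)) {
  orientation <- match.arg(orientation)
  z <- as.matrix(zmatrix)
  z <- z[complete.cases(z), , drop = FALSE]
  p <- ncol(z)
  if (nrow(z) < 10) {
    abort("fit_score_model() needs at least 10 complete rows.",
          class = "metscore_insufficient_data")
  }
  R <- cor(z)
  ee <- eigen(R, symmetric = TRUE)
  lambda <- ee$values
  if (lambda[p] < 1e-10) {
    abort("Trait matrix is rank deficient; correlation matrix is singular.",
          class = "metscore_degenerate_input")
  }
  k <- sum(lambda > eigen_threshold)
  if (k == 0) {
    abort(paste0("No eigenvalue exceeds ", eigen_threshold,
                 "; lower `eigen_threshold` to retain components."),
          class = "metscore_no_component")
  }
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  # loadings = trait-component correlations; unit-variance score weights
  load_un <- V %*% diag(sqrt(lambda[seq_len(k)]), k)
  coef_un <- V %*% diag(1 / sqrt(lambda[seq_len(k)]), k)
  rotated <- rotate && k >= 2
  if (rotated) {
    vm <- varimax(load_un, normalize = TRUE)
    rot <- vm$rotmat
    loadings <- load_un %*% rot
    score_coef <- coef_un %*% rot   # orthogonal rotation keeps scores white
  } else {
    loadings <- load_un
    score_coef <- coef_un
  }
  explained <- colSums(loadings^2) / p
  ord <- order(explained, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  score_coef <- score_coef[, ord, drop = FALSE]
  explained <- explained[ord]
  traits <- colnames(z) %||% paste0("trait", seq_len(p))
  use_adverse <- orientation == "adverse" && all(traits %in% names(adverse_signs))
  for (j in seq_len(k)) {
    flip <- if (use_adverse) {
      sum(adverse_signs[traits] * loadings[, j]) < 0
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (flip) {
      loadings[, j] <- -loadings[, j]
      score_coef[, j] <- -score_coef[, j]
    }
  }
  dimnames(loadings) <- list(traits, paste0("PC", seq_len(k)))
  dimnames(score_coef) <- dimnames(loadings)
  structure(
    list(loadings = loadings, eigenvalues = lambda, explained = explained,
         k = k, rotation = rotated, score_coef = score_coef,
         eigen_threshold = eigen_threshold, traits = traits, n = nrow(z)),
    class = "score_model")
}

score_weights <- function(explained, weighting) {
  switch(weighting,
    proportional = explained / sum(explained),
    equal = rep(1, length(explained)),
    abort(paste0("Unknown weighting '", weighting, "'."),
          class = "metscore_parameter_error"))
}

#' Continuous MetS score from a fitted component model
#'
#' Computes per-individual component scores `s_ik` (unit sample variance on
#' the fitting sample, mutually uncorrelated) and returns their weighted sum
#' `score_i = sum_k w_k s_ik`.  With `weighting = "proportional"` the weights
#' are the explained-variance proportions normalized to sum to one; with
#' `"equal"` each retained component enters with weight 1, in which case the
#' score has sample SD sqrt(K) on the fitting sample.
#'
#' @param model A `score_model` (or `mets_score_model`, see
#'   [fit_mets_score()]).
#' @param data For a `score_model`: the standardized trait matrix; for a
#'   `mets_score_model`: a raw phenotype data frame (transform and
#'   standardization constants stored in the model are applied).
#' @param weighting `"proportional"` (default) or `"equal"`.
#' @param ... Passed between methods.
#' @return Tibble with columns `id` (when available) and `score`; component
#'   scores are attached as attribute `"component_scores"`.
#' @export
compute_scores <- function(model, data, weighting = c("proportional", "equal"), ...) {
  UseMethod("compute_scores")
}

#' @export
compute_scores.score_model <- function(model, data,
                                       weighting = c("proportional", "equal"), ...) {
  weighting <- match.arg(weighting)
  z <- as.matrix(data)
  if (ncol(z) != length(model$traits) ||
      (!is.null(colnames(z)) && !identical(colnames(z), model$traits))) {
    abort(paste0("Column mismatch: model was fitted on ",
                 paste(model$traits, collapse = ", ")),
          class = "metscore_schema_error")
  }
  s <- z %*% model$score_coef
  w <- score_weights(model$explained, weighting)
  out <- tibble::tibble(score = as.numeric(s %*% w))
  attr(out, "component_scores") <- s
  attr(out, "weights") <- w
  out
}

#' Fit the full MetS score pipeline on a phenotype table
#'
#' Convenience wrapper tying together [build_transform_spec()],
#' [standardize_traits()] and [fit_score_model()]: normalizing transforms,
#' standardization, PCA with varimax rotation, and score weights.
#'
#' @param data Phenotype data frame with the [mets_traits()] columns (rows
#'   with a missing trait are dropped listwise for fitting, mirroring the
#'   complete-case design of examination surveys).
#' @param transforms `"fixed"` (apply the designated transforms; default) or
#'   `"screen"` (Shapiro-Wilk screen decides).
#' @param weighting Default weighting for [compute_scores()].
#' @inheritParams fit_score_model
#' @inheritParams build_transform_spec
#' @return Object of class `mets_score_model` bundling the transform spec,
#'   standardization constants and the `score_model`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 300, seed = 7))
#' m <- fit_mets_score(cohort$phenotypes)
#' head(compute_scores(m, cohort$phenotypes))
fit_mets_score <- function(data, transforms = c("fixed", "screen"),
                           alpha = 0.05, eigen_threshold = 1.0, rotate = TRUE,
                           weighting = c("proportional", "equal")) {
  transforms <- match.arg(transforms)
  weighting <- match.arg(weighting)
  cc <- complete.cases(data[mets_traits()])
  fitdat <- data[cc, , drop = FALSE]
  spec <- build_transform_spec(fitdat, mode = transforms, alpha = alpha)
  tdat <- apply_transforms(fitdat, spec)
  std <- standardize_traits(tdat[mets_traits()])
  pca <- fit_score_model(std$z, eigen_threshold = eigen_threshold, rotate = rotate)
  structure(
    list(transform_spec = spec, center = std$center, scale = std$scale,
         pca = pca, weighting = weighting, n = sum(cc)),
    class = "mets_score_model")
}

#' @export
compute_scores.mets_score_model <- function(model, data, weighting = NULL, ...) {
  weighting <- weighting %||% model$weighting
  tdat <- apply_transforms(data, model$transform_spec)
  std <- standardize_traits(tdat[mets_traits()],
                            center = model$center, scale = model$scale)
  out <- compute_scores(model$pca, std$z, weighting = weighting)
  if (!is.null(data[["id"]])) out <- tibble::add_column(out, id = data[["id"]], .before = 1)
  out
}

#' @export
print.score_model <- function(x, ...) {
  cat("PCA score model: ", x$k, " retained component(s)",
      if (x$rotation) " (varimax rotated)", "\n", sep = "")
  cat("Explained variance: ",
      paste0(sprintf("%.2f%%", 100 * x$explained), collapse = ", "),
      " (total ", sprintf("%.2f%%", 100 * sum(x$explained)), ")\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
print.mets_score_model <- function(x, ...) {
  cat("MetS score model fitted on", x$n, "complete records\n")
  cat("Transforms:",
      paste0(x$transform_spec$trait, "=", x$transform_spec$transform, collapse = ", "),
      "\n")
  print(x$pca)
  invisible(x)
}

#' @describeIn fit_mets_score Loadings in long form (one row per trait x
#'   component, `loading` = trait-component correlation).
#' @param x,object A fitted `mets_score_model` or `score_model`.
#' @export
tidy.score_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @export
tidy.mets_score_model <- function(x, ...) tidy(x$pca)

#' @export
glance.score_model <- function(x, ...) {
  tibble::tibble(k = x$k, rotated = x$rotation,
                 prop_variance = sum(x$explained),
                 eigenvalue_1 = x$eigenvalues[1], n = x$n)
}

#' @export
glance.mets_score_model <- function(x, ...) glance(x$pca)

#' @export
autoplot.score_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$loading, y = .data$trait,
                                 fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~component) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Trait-component correlation", y = NULL,
                  title = "MetS score component loadings")
}

#' @export
autoplot.mets_score_model <- function(object, ...) autoplot(object$pca, ...)

#' ANOVA linear-trend test across ordered groups
#'
#' Single-degree-of-freedom linear contrast across ordered group means, with
#' contrast coefficients equal to the centered group codes and the error term
#' taken from the pooled within-group mean square.
#'
#' @param values Numeric outcome vector.
#' @param ordinal_group Integer-valued group codes (at least two distinct
#'   levels, each non-empty).
#' @return One-row tibble: `estimate` (contrast value), `statistic` (F),
#'   `df1`, `df2`, `p_value`.
#' @export
anova_trend <- function(values, ordinal_group) {
  keep <- !is.na(values) & !is.na(ordinal_group)
  y <- values[keep]
  g <- ordinal_group[keep]
  codes <- sort(unique(g))
  if (length(codes) < 2) {
    abort("anova_trend() needs at least two ordinal levels.",
          class = "metscore_insufficient_data")
  }
  means <- vapply(codes, function(cd) mean(y[g == cd]), numeric(1))
  ns <- vapply(codes, function(cd) sum(g == cd), numeric(1))
  N <- length(y)
  J <- length(codes)
  sse <- sum(vapply(codes, function(cd) sum((y[g == cd] - mean(y[g == cd]))^2),
                    numeric(1)))
  df2 <- N - J
  if (df2 <= 0 || sse <= 0) {
    abort("anova_trend(): no within-group variance to form the error term.",
          class = "metscore_degenerate_input")
  }
  mse <- sse / df2
  cc <- codes - mean(codes)
  L <- sum(cc * means)
  se2 <- mse * sum(cc^2 / ns)
  Fstat <- L^2 / se2
  tibble::tibble(estimate = L, statistic = Fstat, df1 = 1, df2 = df2,
                 p_value = pf(Fstat, 1, df2, lower.tail = FALSE))
}

#' Score validity report: trend over risk counts and MetS group contrast
#'
#' Checks the two face-validity properties of the continuous score: it should
#' rise linearly with the number of dichotomous risk factors, and be markedly
#' higher in participants meeting the dichotomous MetS definition.
#'
#' @param scores Numeric score vector.
#' @param mets_status Logical MetS flag per individual.
#' @param risk_counts Integer number of risk features (0-5) per individual.
#' @return List of class `score_validation`: `trend` (from [anova_trend()]),
#'   `group_means` (per risk count), `comparison` (pooled two-sample t of
#'   MetS vs non-MetS, `NULL` with a warning if only one status present).
#' @export
validate_score <- function(scores, mets_status, risk_counts) {
  stopifnot(length(scores) == length(mets_status),
            length(scores) == length(risk_counts))
  trend <- anova_trend(scores, risk_counts)
  gm <- tibble::tibble(risk_count = risk_counts, score = scores) |>
    dplyr::filter(!is.na(.data$risk_count), !is.na(.data$score)) |>
    dplyr::group_by(.data$risk_count) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$risk_count)
  st <- mets_status[!is.na(mets_status) & !is.na(scores)]
  sc <- scores[!is.na(mets_status) & !is.na(scores)]
  comparison <- NULL
  if (length(unique(st)) < 2) {
    warn("All individuals share the same MetS status; group comparison skipped.")
  } else {
    comparison <- t_test_raw(sc[st], sc[!st])
    comparison <- tibble::add_column(comparison,
                                     group1 = "MetS", group2 = "no MetS",
                                     .before = 1)
  }
  structure(list(trend = trend, group_means = gm, comparison = comparison),
            class = "score_validation")
}

#' @export
print.score_validation <- function(x, ...) {
  cat("Linear trend across risk-factor counts: F =",
      sprintf("%.2f", x$trend$statistic),
      ", p =", format.pval(x$trend$p_value, digits = 3), "\n")
  print(x$group_means)
  if (!is.null(x$comparison)) {
    cat(sprintf("MetS vs no MetS: %.2f +/- %.2f vs %.2f +/- %.2f, p = %s\n",
                x$comparison$mean1, x$comparison$sd1,
                x$comparison$mean2, x$comparison$sd2,
                format.pval(x$comparison$p_value, digits = 3)))
  }
  invisible(x)
}

#' @export
autoplot.score_validation <- function(object, ...) {
  object$group_means |>
    ggplot2::ggplot(ggplot2::aes(x = .data$risk_count, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "Number of MetS risk factors", y = "Mean MetS score",
                  subtitle = sprintf("Linear trend p = %s",
                                     format.pval(object$trend$p_value, digits = 3)))
}

#' Serialize a fitted MetS score model to a plain-text file
#'
#' Versioned key-value/TSV hybrid format carrying the transform spec,
#' standardization constants, loadings, eigenvalues and explained variance,
#' sufficient to score a new cohort with [read_score_model()] +
#' [compute_scores()].
#'
#' @param model A `mets_score_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) cat(..., "\n", sep = "", file = con)
  wr("metscore_model\t1")
  wr("n\t", model$n)
  wr("weighting\t", model$weighting)
  wr("rotation\t", model$pca$rotation)
  wr("k\t", model$pca$k)
  wr("eigenvalues\t", paste(format(model$pca$eigenvalues, digits = 17), collapse = "\t"))
  wr("explained\t", paste(format(model$pca$explained, digits = 17), collapse = "\t"))
  for (tr in model$pca$traits) {
    i <- match(tr, model$transform_spec$trait)
    wr("trait\t", tr, "\t", model$transform_spec$transform[i], "\t",
       format(model$center[[tr]], digits = 17), "\t",
       format(model$scale[[tr]], digits = 17), "\t",
       paste(format(model$pca$loadings[tr, ], digits = 17), collapse = "\t"), "\t",
       paste(format(model$pca$score_coef[tr, ], digits = 17), collapse = "\t"))
  }
  invisible(path)
}

#' Read a serialized MetS score model
#'
#' @param path File written by [write_score_model()].
#' @return A `mets_score_model`.
#' @export
read_score_model <- function(path) {
  lines <- readr::read_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (fields[[1]][1] != "metscore_model") {
    abort("Not a metscore model file.", class = "metscore_schema_error")
  }
  get1 <- function(key) {
    f <- fields[[which(vapply(fields, `[`, "", 1) == key)[1]]]
    f[-1]
  }
  k <- as.integer(get1("k"))
  trait_rows <- fields[vapply(fields, `[`, "", 1) == "trait"]
  traits <- vapply(trait_rows, `[`, "", 2)
  tf <- vapply(trait_rows, `[`, "", 3)
  center <- setNames(as.numeric(vapply(trait_rows, `[`, "", 4)), traits)
  scale <- setNames(as.numeric(vapply(trait_rows, `[`, "", 5)), traits)
  loadings <- do.call(rbind, lapply(trait_rows, function(f)
    as.numeric(f[6:(5 + k)])))
  score_coef <- do.call(rbind, lapply(trait_rows, function(f)
    as.numeric(f[(6 + k):(5 + 2 * k)])))
  dimnames(loadings) <- list(traits, paste0("PC", seq_len(k)))
  dimnames(score_coef) <- dimnames(loadings)
  spec <- tibble::tibble(trait = traits, statistic = NA_real_, p_value = NA_real_,
                         transform = tf, mean = center, sd = scale)
  class(spec) <- c("transform_spec", class(spec))
  pca <- structure(
    list(loadings = loadings, eigenvalues = as.numeric(get1("eigenvalues")),
         explained = as.numeric(get1("explained")), k = k,
         rotation = as.logical(get1("rotation")), score_coef = score_coef,
         eigen_threshold = 1.0, traits = traits, n = as.integer(get1("n"))),
    class = "score_model")
  structure(list(transform_spec = spec, center = center, scale = scale,
                 pca = pca, weighting = get1("weighting"),
                 n = as.integer(get1("n"))),
            class = "mets_score_model")
}
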