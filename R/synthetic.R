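# Synthetic-cohort generator.  Emulates the statistical structure the score
# construction assumes: six traits whose transformed, standardized values
# load on two latent factors (a blood-pressure/waist/glucose axis and a
# lipid axis), genotypes drawn in Hardy-Weinberg equilibrium at the panel
# MAFs, covariates at the survey prevalences, and optional dominance-model
# effects of chosen SNPs on the first latent factor.  All defaults are
# documented conventions, not estimates from any individual-level data.

#' Default candidate-SNP panel
#'
#' The 37 candidate SNPs (gene, rs id, minor-allele frequency) spanning
#' glucose/insulin homeostasis, cardiovascular regulation, body-mass-index
#' and lipid/drug-metabolism genes that the association workflow targets.
#'
#' @return Tibble with columns `gene`, `snp_id`, `maf`.
#' @export
default_snp_panel <- function() {
  tibble::tribble(
    ~gene, ~snp_id, ~maf,
    "CDKAL1", "rs7754840", 0.286,
    "CDKN2A/B", "rs10811661", 0.201,
    "HHEX", "rs1111875", 0.371,
    "IGF2BP2", "rs4402960", 0.272,
    "IL6", "rs1800795", 0.337,
    "KCNJ11", "rs5219", 0.333,
    "KCNQ1", "rs2237892", 0.051,
    "MTNR1B", "rs10830963", 0.223,
    "PPARG", "rs1801282", 0.093,
    "SLC30A8", "rs13266634", 0.286,
    "TCF7L2", "rs7903146", 0.303,
    "ADCY5", "rs11708067", 0.199,
    "KCNQ1", "rs231362", 0.234,
    "ACE", "rs4646994", 0.420,
    "NOS1AP", "rs12143842", 0.265,
    "ADRB1", "rs1801252", 0.108,
    "ADRB2", "rs1042714", 0.407,
    "ADRB2", "rs1042713", 0.362,
    "NOS3", "rs1799983", 0.417,
    "LDLR", "rs2228671", 0.124,
    "NOS3", "rs2070744", 0.451,
    "GNPDA2", "rs10938397", 0.481,
    "MTCH2", "rs10838738", 0.282,
    "NPC1", "rs1805081", 0.288,
    "PTER", "rs10508503", 0.075,
    "SH2B1", "rs7498665", 0.303,
    "FTO", "rs9939609", 0.361,
    "ADRB3", "rs4994", 0.090,
    "GABRA2", "rs279871", 0.434,
    "NPY", "rs16147", 0.450,
    "TMEM18", "rs6548238", 0.127,
    "APOE", "rs7412", 0.027,
    "CYP2C8", "rs10509681", 0.129,
    "CYP2C9", "rs1799853", 0.138,
    "CYP2D6", "rs16947", 0.393,
    "CYP2C19", "rs4244285", 0.129,
    "TPMT", "rs1142345", 0.032)
}

#' Default latent-factor loadings for the six transformed traits
#'
#' Loadings of the transformed, standardized traits on the two latent
#' factors: factor 1 carries blood pressure, waist circumference and glucose
#' (glucose negative because its normalizing transform is decreasing),
#' factor 2 carries the lipids (HDL negative: its transform is increasing
#' but high HDL is protective of the lipid axis as oriented here).
#'
#' @return 6 x 2 numeric matrix, rows named by [mets_traits()].
#' @export
default_factor_loadings <- function() {
  L <- matrix(c(
    0.650, 0.255,
    0.771, 0.320,
    0.826, 0.057,
    -0.598, 0.147,
    0.079, -0.885,
    0.305, 0.818), ncol = 2, byrow = TRUE,
    dimnames = list(mets_traits(), c("F1", "F2")))
  L
}

#' Default raw-trait targets (mean and SD) for the generator
#'
#' Location/scale the generated raw traits aim for: waist 95.50 (12.56) cm,
#' DBP 80.67 (9.96) and SBP 131.72 (20.02) mmHg, glucose 103.29 (33.91),
#' HDL 53.51 (13.33) and TG 107.71 (60.29) mg/dL — typical of a middle-aged
#' southern-European examination-survey population.  The match is
#' approximate: the generator fixes the transformed-scale moments by the
#' delta method, so raw moments inherit the transforms' curvature.
#'
#' @return Tibble `trait`, `mean`, `sd`.
#' @export
default_trait_targets <- function() {
  tibble::tibble(
    trait = mets_traits(),
    mean = c(95.50, 80.67, 131.72, 103.29, 53.51, 107.71),
    sd = c(12.56, 9.96, 20.02, 33.91, 13.33, 60.29))
}

# delta-method derivative of each transform at x
transform_deriv <- function(x, transform) {
  switch(transform,
    identity = rep(1, length(x)),
    log10log10 = 1 / (x * log(10)^2 * log10(x)),
    inv_log10_pow10 = -10 * log10(x)^(-11) / (x * log(10)),
    sq_ln = 2 * log(x) / x)
}

#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every generator knob.  Defaults emulate a
#' middle-aged examination-survey cohort of 206 participants: two latent
#' factors with [default_factor_loadings()], per-trait uniqueness equal to
#' one minus the communality, genotypes at the [default_snp_panel()] MAFs,
#' covariate prevalences (female 57.8%, smoker 18.0%, excessive alcohol
#' 8.7%, physical inactivity 59.7%, unhealthy diet 35.9%, antihypertensive
#' 26.2%, lipid-lowering 12.6%, antidiabetic 7.3%) and age 56.4 (16.2)
#' years truncated to 26-91.
#'
#' @param n_individuals Cohort size (default 206).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param factor_loadings 6 x 2 loading matrix on the transformed,
#'   standardized trait scale (rows in [mets_traits()] order).
#' @param uniqueness_variances Per-trait unique variances; default
#'   `1 - rowSums(loadings^2)` so communality + uniqueness = 1.
#' @param snp_panel Tibble `gene`, `snp_id`, `maf` with MAFs in `[0, 0.5]`.
#' @param genetic_effects Tibble `snp_id`, `beta`, `model` (only
#'   `"dominant"`); carriers of each listed SNP have latent factor 1 shifted
#'   by `beta`.  Default: no effects.
#' @param covariate_prevalences Named numeric vector of prevalences for
#'   `female`, `smoker`, `excess_alcohol`, `inactive`, `unhealthy_diet`,
#'   `med_htn`, `med_chol`, `med_diab`.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param trait_targets Tibble `trait`, `mean`, `sd` of raw-trait targets;
#'   converted to transformed-scale location/scale by the delta method.
#' @param age_effect Linear effect of standardized age on latent factor 1
#'   (default 0; switch on to make covariate adjustment testable).
#' @param age_genotype_assoc Log-odds shift of effect-SNP allele frequency
#'   per SD of age (default 0; nonzero makes age a genuine confounder).
#' @param max_retries Redraw attempts for rows whose sampled transformed
#'   values fall outside the inverse-transform domain.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 206, seed = NULL,
                             factor_loadings = default_factor_loadings(),
                             uniqueness_variances = NULL,
                             snp_panel = default_snp_panel(),
                             genetic_effects = NULL,
                             covariate_prevalences = c(
                               female = 0.5777, smoker = 0.1796,
                               excess_alcohol = 0.0874, inactive = 0.5971,
                               unhealthy_diet = 0.3592, med_htn = 0.2621,
                               med_chol = 0.1260, med_diab = 0.0730),
                             age_mean = 56.43, age_sd = 16.23,
                             age_range = c(26, 91),
                             trait_targets = default_trait_targets(),
                             age_effect = 0, age_genotype_assoc = 0,
                             max_retries = 100) {
  L <- as.matrix(factor_loadings)
  if (!identical(dim(L), c(6L, 2L))) {
    abort("factor_loadings must be a 6 x 2 matrix.",
          class = "metscore_parameter_error")
  }
  communality <- rowSums(L^2)
  uniqueness_variances <- uniqueness_variances %||% (1 - communality)
  if (any(uniqueness_variances <= 0) ||
      any(abs(communality + uniqueness_variances - 1) > 1e-8)) {
    abort("communality + uniqueness must equal 1 per trait (uniqueness > 0).",
          class = "metscore_parameter_error")
  }
  if (any(snp_panel$maf < 0 | snp_panel$maf > 0.5)) {
    abort("Panel MAFs must lie in [0, 0.5].", class = "metscore_parameter_error")
  }
  genetic_effects <- genetic_effects %||%
    tibble::tibble(snp_id = character(), beta = numeric(), model = character())
  if (nrow(genetic_effects) > 0) {
    if (!all(genetic_effects$model == "dominant")) {
      abort("Only the dominant effect model is supported.",
            class = "metscore_parameter_error")
    }
    orphan <- setdiff(genetic_effects$snp_id, snp_panel$snp_id)
    if (length(orphan) > 0) {
      abort(paste0("Effect SNP(s) missing from panel: ",
                   paste(orphan, collapse = ", ")),
            class = "metscore_parameter_error")
    }
  }
  need_prev <- c("female", "smoker", "excess_alcohol", "inactive",
                 "unhealthy_diet", "med_htn", "med_chol", "med_diab")
  if (!all(need_prev %in% names(covariate_prevalences)) ||
      any(covariate_prevalences < 0 | covariate_prevalences > 1)) {
    abort("covariate_prevalences must name all eight flags with values in [0, 1].",
          class = "metscore_parameter_error")
  }
  if (n_individuals < 1) abort("n_individuals must be positive.",
                               class = "metscore_parameter_error")
  stopifnot(identical(trait_targets$trait, mets_traits()))
  tf <- default_transforms()
  # Delta-method transformed-scale moments; where the transform needs a
  # strictly positive value (all but identity) the scale is capped at a
  # quarter of the location so essentially no draw leaves the valid domain.
  # Only glucose hits the cap: its reciprocal-tenth-power transform is too
  # sharp for a Gaussian transformed value to reproduce the full raw-scale
  # dispersion, so the generated raw glucose SD is compressed (documented).
  loc_scale <- trait_targets |>
    dplyr::mutate(transform = unname(tf[.data$trait]),
                  location = purrr::map2_dbl(.data$mean, .data$transform,
                                             ~ transform_trait(.x, .y)),
                  scale = abs(purrr::pmap_dbl(
                    list(.data$mean, .data$transform, .data$sd),
                    function(m, t, s) transform_deriv(m, t) * s)),
                  scale = ifelse(.data$transform == "identity", .data$scale,
                                 pmin(.data$scale, .data$location / 4)))
  structure(
    list(n_individuals = as.integer(n_individuals), seed = seed,
         factor_loadings = L, uniqueness_variances = uniqueness_variances,
         snp_panel = snp_panel, genetic_effects = genetic_effects,
         covariate_prevalences = covariate_prevalences,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         trait_location_scale = loc_scale,
         age_effect = age_effect, age_genotype_assoc = age_genotype_assoc,
         max_retries = max_retries),
    class = "synthetic_config")
}

#' Draw genotype dosages in Hardy-Weinberg equilibrium
#'
#' Minor-allele dosages are binomial(2, q), i.e. genotype probabilities
#' `(1-q)^2, 2q(1-q), q^2`.
#'
#' @param n Number of individuals.
#' @param maf Minor-allele frequency in `[0, 0.5]`.
#' @param seed Optional integer seed.
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
generate_genotypes <- function(n, maf, seed = NULL) {
  if (maf < 0 || maf > 0.5) {
    abort("maf must lie in [0, 0.5].", class = "metscore_parameter_error")
  }
  if (n < 1) abort("n must be >= 1.", class = "metscore_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 2L, maf)
}

#' Shift latent values of minor-allele carriers
#'
#' Dominance coding: individuals with dosage >= 1 are shifted by `beta`,
#' major-allele homozygotes are unchanged.  Missing dosages leave the latent
#' value unshifted.
#'
#' @param latent Numeric latent-score vector.
#' @param dosages Dosage vector of equal length.
#' @param beta Shift applied to carriers.
#' @param model Effect model; only `"dominant"` is defined.
#' @return Shifted latent vector.
#' @export
apply_genetic_effect <- function(latent, dosages, beta, model = "dominant") {
  if (!identical(model, "dominant")) {
    abort(paste0("Unknown effect model '", model, "'."),
          class = "metscore_parameter_error")
  }
  if (length(latent) != length(dosages)) {
    abort("latent and dosages must have equal length.",
          class = "metscore_parameter_error")
  }
  carrier <- !is.na(dosages) & dosages >= 1
  latent + beta * carrier
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws covariates, genotypes and the latent two-factor trait structure of
#' a [synthetic_config()], applies any configured dominance effects to
#' latent factor 1 before trait generation, maps standardized transformed
#' traits to realistic transformed-scale values and inverts the normalizing
#' transforms to raw units.  Rows whose sampled transformed values fall
#' outside an inverse-transform domain (e.g. a glucose transform value at or
#' below zero) are redrawn up to `max_retries` times.
#'
#' @param config A `synthetic_config`.
#' @return List with `phenotypes` (tibble in the standard column layout),
#'   `genotypes` (tibble `id` + one dosage column per panel SNP), `truth`
#'   (tibble `id`, `factor1`, `factor2`, `latent_score` = factor 1, the axis
#'   genetic effects act on) and the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 50, seed = 42))
#' dplyr::glimpse(cohort$phenotypes)
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().",
          class = "metscore_parameter_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  prev <- config$covariate_prevalences
  id <- sprintf("S%05d", seq_len(n))

  age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  z_age <- (age - config$age_mean) / config$age_sd
  sex <- ifelse(runif(n) < prev[["female"]], "female", "male")
  flags <- purrr::map(c("smoker", "excess_alcohol", "inactive",
                        "unhealthy_diet", "med_htn", "med_chol", "med_diab"),
                      ~ runif(n) < prev[[.x]])
  names(flags) <- c("smoker", "excess_alcohol", "inactive", "unhealthy_diet",
                    "med_htn", "med_chol", "med_diab")

  # genotypes: HWE draws; effect SNPs optionally age-associated (confounding)
  effect_ids <- config$genetic_effects$snp_id
  geno <- purrr::map(seq_len(nrow(config$snp_panel)), function(i) {
    q <- config$snp_panel$maf[i]
    sid <- config$snp_panel$snp_id[i]
    if (config$age_genotype_assoc != 0 && sid %in% effect_ids && q > 0) {
      qi <- plogis(qlogis(q) + config$age_genotype_assoc * z_age)
      rbinom(n, 2L, qi)
    } else {
      rbinom(n, 2L, q)
    }
  })
  names(geno) <- config$snp_panel$snp_id
  genotypes <- tibble::as_tibble(c(list(id = id), geno))

  # latent factor shift from dominance effects + optional age term
  shift <- rep(0, n)
  if (nrow(config$genetic_effects) > 0) {
    for (i in seq_len(nrow(config$genetic_effects))) {
      shift <- apply_genetic_effect(shift,
                                    genotypes[[config$genetic_effects$snp_id[i]]],
                                    config$genetic_effects$beta[i],
                                    config$genetic_effects$model[i])
    }
  }
  shift <- shift + config$age_effect * z_age

  L <- config$factor_loadings
  sqrt_psi <- sqrt(config$uniqueness_variances)
  ls <- config$trait_location_scale
  draw_rows <- function(m) {
    f1 <- rnorm(m)
    f2 <- rnorm(m)
    E <- matrix(rnorm(m * 6), m, 6)
    list(f1 = f1, f2 = f2, E = E)
  }
  assemble <- function(f1_shifted, f2, E) {
    Tstd <- cbind(f1_shifted, f2) %*% t(L) + sweep(E, 2, sqrt_psi, "*")
    sweep(sweep(Tstd, 2, ls$scale, "*"), 2, ls$location, "+")
  }
  valid_rows <- function(tmat) {
    ok <- rep(TRUE, nrow(tmat))
    for (j in seq_len(6)) {
      v <- tmat[, j]
      ok <- ok & switch(ls$transform[j],
        identity = v > 0,
        log10log10 = v > 0,           # keeps raw value above 10
        inv_log10_pow10 = v > 0 & v < 1,  # raw glucose in (10, Inf)
        sq_ln = v > 0)
    }
    ok
  }
  dr <- draw_rows(n)
  f1 <- dr$f1 + shift
  f2 <- dr$f2
  tmat <- assemble(f1, f2, dr$E)
  ok <- valid_rows(tmat)
  tries <- 0
  while (any(!ok)) {
    tries <- tries + 1
    if (tries > config$max_retries) {
      abort(paste0("generate_cohort(): ", sum(!ok), " row(s) still outside the ",
                   "inverse-transform domain after ", config$max_retries,
                   " redraws; check trait targets/loadings."),
            class = "metscore_domain_error")
    }
    idx <- which(!ok)
    rd <- draw_rows(length(idx))
    f1[idx] <- rd$f1 + shift[idx]
    f2[idx] <- rd$f2
    tmat[idx, ] <- assemble(f1[idx], f2[idx], rd$E)
    ok[idx] <- valid_rows(tmat[idx, , drop = FALSE])
  }
  raw <- purrr::map(seq_len(6), function(j) {
    inverse_transform_trait(tmat[, j], ls$transform[j])
  })
  names(raw) <- ls$trait

  phenotypes <- tibble::as_tibble(c(
    list(id = id), raw,
    list(sex = sex, age_years = age), flags))[phenotype_columns()]
  truth <- tibble::tibble(id = id, factor1 = f1, factor2 = f2,
                          latent_score = f1)
  list(phenotypes = phenotypes, genotypes = genotypes, truth = truth,
       config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `phenotypes.csv`, `genotypes.csv` and `truth.tsv` (latent factors
#' and configured effects) into a directory.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_csv(cohort$genotypes, file.path(dir, "genotypes.csv"))
  truth <- cohort$truth
  eff <- cohort$config$genetic_effects
  if (nrow(eff) > 0) {
    truth <- dplyr::mutate(truth,
      injected_effects = paste(paste0(eff$snp_id, "=", eff$beta), collapse = ";"))
  }
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
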