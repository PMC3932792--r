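test_that("two-factor synthetic data recovers two components and the generative explained variance", {
  coh <- generate_cohort(synthetic_config(n = 5000, seed = 101))
  m <- fit_mets_score(coh$phenotypes)
  expect_identical(m$pca$k, 2L)
  target <- population_explained(default_factor_loadings(), k = 2)
  expect_lt(abs(sum(m$pca$explained) - target), 0.05)
  # fitted loadings lie in [-1, 1] and the lipid axis has the adverse shape:
  # TG positive, HDL negative
  expect_true(all(abs(m$pca$loadings) <= 1 + 1e-12))
  lipid <- which.max(abs(m$pca$loadings["hdl_mg_dl", ]))
  expect_gt(m$pca$loadings["tg_mg_dl", lipid], 0)
  expect_lt(m$pca$loadings["hdl_mg_dl", lipid], 0)
})

test_that("isotropic data keeps all eigenvalues near one and the strict rule holds", {
  withr::with_seed(55, z <- matrix(rnorm(10000 * 6), ncol = 6,
                                   dimnames = list(NULL, mets_traits())))
  z <- standardize_traits(z)$z
  m <- fit_score_model(z)
  expect_true(all(abs(m$eigenvalues - 1) < 0.1))
  expect_identical(m$k, sum(m$eigenvalues > 1.0))
  expect_error(fit_score_model(z, eigen_threshold = 2),
               class = "metscore_no_component")
})

test_that("rank-deficient input is rejected with a degeneracy error", {
  withr::with_seed(4, z <- matrix(rnorm(300), ncol = 3))
  z <- cbind(z, z[, 1] * 2 + z[, 2], z[, 2], z[, 3])
  z <- standardize_traits(z)$z
  colnames(z) <- mets_traits()
  expect_error(fit_score_model(z), class = "metscore_degenerate_input")
})

test_that("component orientation follows the requested convention", {
  coh <- generate_cohort(synthetic_config(n = 1500, seed = 77))
  tdat <- apply_transforms(coh$phenotypes, build_transform_spec(coh$phenotypes))
  z <- standardize_traits(tdat[mets_traits()])$z
  m_max <- fit_score_model(z, orientation = "max_loading")
  for (j in seq_len(m_max$k)) {
    expect_gt(m_max$loadings[which.max(abs(m_max$loadings[, j])), j], 0)
  }
  adverse <- c(waist_cm = 1, dbp_mmHg = 1, sbp_mmHg = 1,
               glucose_mg_dl = -1, hdl_mg_dl = -1, tg_mg_dl = 1)
  m_adv <- fit_score_model(z, orientation = "adverse")
  for (j in seq_len(m_adv$k)) {
    expect_gt(sum(adverse * m_adv$loadings[, j]), 0)
  }
})

test_that("retained component scores are uncorrelated with unit variance", {
  coh <- generate_cohort(synthetic_config(n = 2000, seed = 13))
  tdat <- apply_transforms(coh$phenotypes, build_transform_spec(coh$phenotypes))
  z <- standardize_traits(tdat[mets_traits()])$z
  for (rot in c(TRUE, FALSE)) {
    m <- fit_score_model(z, rotate = rot)
    s <- attr(compute_scores(m, z), "component_scores")
    expect_equal(apply(s, 2, sd), rep(1, m$k), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(abs(cor(s[, 1], s[, 2])), 1e-9)
  }
})

test_that("equal weighting with two components gives score SD sqrt(2) and mean 0", {
  coh <- generate_cohort(synthetic_config(n = 3000, seed = 29))
  m <- fit_mets_score(coh$phenotypes)
  sc <- compute_scores(m, coh$phenotypes, weighting = "equal")
  expect_equal(sd(sc$score), sqrt(2), tolerance = 1e-9)
  expect_lt(abs(mean(sc$score)), 1e-9)
  # proportional weights shrink the dispersion below sqrt(2)
  scp <- compute_scores(m, coh$phenotypes, weighting = "proportional")
  expect_lt(sd(scp$score), sqrt(2))
  expect_lt(abs(mean(scp$score)), 1e-9)
})

test_that("a single retained component reproduces its own score exactly", {
  # one dominant factor: only the first eigenvalue exceeds 1
  withr::with_seed(31, {
    f <- rnorm(2000)
    z <- sapply(seq_len(6), function(j) 0.9 * f + sqrt(1 - 0.81) * rnorm(2000))
  })
  colnames(z) <- mets_traits()
  z <- standardize_traits(z)$z
  m <- fit_score_model(z)
  expect_identical(m$k, 1L)
  sc <- compute_scores(m, z)
  s <- attr(sc, "component_scores")
  expect_equal(sc$score, as.numeric(s[, 1]), tolerance = 1e-12)
  expect_equal(compute_scores(m, z, weighting = "equal")$score, sc$score,
               tolerance = 1e-12)
})

test_that("raising one individual's TG raises their score under the fitted model", {
  coh <- generate_cohort(synthetic_config(n = 2000, seed = 41))
  m <- fit_mets_score(coh$phenotypes)
  p <- coh$phenotypes[3, ]
  s0 <- compute_scores(m, p)$score
  p$tg_mg_dl <- p$tg_mg_dl * 1.3
  expect_gt(compute_scores(m, p)$score, s0)
})

test_that("score is invariant to affine rescaling of an untransformed trait", {
  coh <- generate_cohort(synthetic_config(n = 800, seed = 59))
  m1 <- fit_mets_score(coh$phenotypes)
  s1 <- compute_scores(m1, coh$phenotypes)$score
  resc <- dplyr::mutate(coh$phenotypes, waist_cm = 2 * waist_cm + 5)
  m2 <- fit_mets_score(resc)
  s2 <- compute_scores(m2, resc)$score
  expect_equal(s2, s1, tolerance = 1e-9)
})

test_that("column mismatch with the fitted model is a schema error", {
  coh <- generate_cohort(synthetic_config(n = 200, seed = 2))
  tdat <- apply_transforms(coh$phenotypes, build_transform_spec(coh$phenotypes))
  z <- standardize_traits(tdat[mets_traits()])$z
  m <- fit_score_model(z)
  expect_error(compute_scores(m, z[, c(2, 1, 3:6)]),
               class = "metscore_schema_error")
})

test_that("trend test: flat means give p of one, constructed trend is detected", {
  withr::with_seed(8, noise <- rnorm(250, sd = 0.1))
  flat <- rep(5, 250) + noise
  g <- rep(1:5, each = 50)
  res <- anova_trend(flat - ave(flat, g) + 5, g)  # exactly equal group means
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  trended <- g + noise
  expect_lt(anova_trend(trended, g)$p_value, 1e-6)
  expect_error(anova_trend(rnorm(10), rep(1, 10)),
               class = "metscore_insufficient_data")
})

test_that("trend test equals the regression slope test for two balanced groups", {
  withr::with_seed(77, y <- rnorm(80) + rep(c(0, 0.4), each = 40))
  g <- rep(1:2, each = 40)
  ours <- anova_trend(y, g)
  fit <- summary(lm(y ~ g))
  expect_equal(ours$p_value, fit$coefficients["g", "Pr(>|t|)"],
               tolerance = 1e-6)
  expect_equal(ours$statistic, fit$coefficients["g", "t value"]^2,
               tolerance = 1e-8)
})

test_that("score validity: trend across risk counts and separation by status", {
  coh <- generate_cohort(synthetic_config(n = 1000, seed = 63))
  m <- fit_mets_score(coh$phenotypes)
  sc <- compute_scores(m, coh$phenotypes)
  st <- classify_mets(coh$phenotypes)
  v <- validate_score(sc$score, st$mets, st$risk_count)
  expect_lt(v$trend$p_value, 0.001)
  expect_gt(v$comparison$mean1, v$comparison$mean2)
  expect_lt(v$comparison$p_value, 0.001)
  # degenerate: uniform status skips the comparison with a warning
  expect_warning(v2 <- validate_score(sc$score, rep(TRUE, nrow(st)),
                                      st$risk_count))
  expect_null(v2$comparison)
})

test_that("permuted MetS labels give a null comparison about 5% of the time", {
  coh <- generate_cohort(synthetic_config(n = 400, seed = 17))
  m <- fit_mets_score(coh$phenotypes)
  sc <- compute_scores(m, coh$phenotypes)
  st <- classify_mets(coh$phenotypes)
  withr::with_seed(99, {
    hits <- vapply(seq_len(200), function(i) {
      lab <- sample(st$mets)
      t_test_raw(sc$score[lab], sc$score[!lab])$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.12)
})

test_that("fitted score model serializes to text and scores a new cohort identically", {
  coh <- generate_cohort(synthetic_config(n = 500, seed = 83))
  m <- fit_mets_score(coh$phenotypes)
  path <- withr::local_tempfile(fileext = ".txt")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  new <- generate_cohort(synthetic_config(n = 100, seed = 84))$phenotypes
  expect_equal(compute_scores(m2, new)$score, compute_scores(m, new)$score,
               tolerance = 1e-10)
})

test_that("tidy and glance expose loadings and fit summary", {
  coh <- generate_cohort(synthetic_config(n = 300, seed = 5))
  m <- fit_mets_score(coh$phenotypes)
  td <- tidy(m)
  expect_identical(nrow(td), 12L)
  expect_named(td, c("trait", "component", "loading"))
  gl <- glance(m)
  expect_identical(gl$k, 2L)
  expect_s3_class(autoplot(m), "ggplot")
})
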