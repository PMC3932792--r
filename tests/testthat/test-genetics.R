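test_that("minor allele frequency counts alleles with pairwise deletion", {
  expect_equal(maf(rep(0, 10)), 0)
  expect_equal(maf(rep(1, 10)), 0.5)
  expect_equal(maf(c(0, 0, 1, 2)), 0.375)
  expect_equal(maf(c(0, 1, NA, NA)), 0.25)
  expect_error(maf(c(NA, NA)), class = "metscore_insufficient_data")
  expect_error(maf(c(0, 3)), class = "metscore_parameter_error")
})

test_that("HWE chi-square matches hand-computed expectations", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$statistic, 0, tolerance = 1e-12)
  expect_equal(perfect$p_value, 1, tolerance = 1e-12)

  # q = 0.5, expected (7.5, 15, 7.5): chi2 = 2.5^2/7.5 + 5^2/15 + 2.5^2/7.5
  r <- hwe_test(10, 10, 10)
  expect_equal(r$maf, 0.5)
  expect_equal(r$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(10 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(r$p_value, 4), 0.0679)

  # maximal heterozygote excess: all expected mass violated, chi2 = n
  ext <- hwe_test(0, 100, 0)
  expect_equal(ext$statistic, 100, tolerance = 1e-10)
  expect_lt(ext$p_value, 0.001)

  expect_error(hwe_test(50, 0, 0), class = "metscore_degenerate_input")
  expect_error(hwe_test(-1, 2, 3), class = "metscore_parameter_error")
})

test_that("HWE p-values on equilibrium draws are well calibrated", {
  withr::with_seed(2024, {
    ps <- vapply(seq_len(1000), function(i) {
      d <- generate_genotypes(500, 0.3)
      hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p_value
    }, numeric(1))
  })
  expect_gt(mean(ps > 0.001), 0.99)
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("dominance grouping separates carriers from reference homozygotes", {
  g <- group_dominant(c(0, 1, 2, 0))
  expect_identical(g$reference, c(1L, 4L))
  expect_identical(g$carrier, c(2L, 3L))
  # missing dosages fall in neither group
  g2 <- group_dominant(c(0, NA, 2))
  expect_identical(g2$reference, 1L)
  expect_identical(g2$carrier, 3L)
  # all carriers leaves the reference empty; downstream test must refuse
  g3 <- group_dominant(c(1, 2, 1))
  expect_length(g3$reference, 0)
  # a 206-cohort split with 156 reference / 43+7 carriers
  d <- c(rep(0, 156), rep(1, 43), rep(2, 7))
  g4 <- group_dominant(d)
  expect_length(g4$reference, 156)
  expect_length(g4$carrier, 50)
})

test_that("summary-statistic t-test reproduces published genotype-group contrasts", {
  # protective carrier group: large positive reference-minus-carrier difference
  r <- t_test_summary(156, 0.192, 1.380, 50, -0.600, 1.362)
  expect_equal(r$estimate, 0.792, tolerance = 1e-12)
  expect_equal(r$df, 204)
  expect_equal(r$p_value, 0.000491114, tolerance = 1e-6)
  expect_equal(round(c(r$conf_low, r$conf_high), 3), c(0.351, 1.233))

  # small carrier group with higher scores: negative difference, p ~ 0.003
  r2 <- t_test_summary(192, -0.080, 1.375, 13, 1.119, 1.601)
  expect_equal(r2$estimate, -1.199, tolerance = 1e-12)
  expect_equal(round(r2$p_value, 3), 0.003)

  r3 <- t_test_summary(10, 1, 1, 10, 1, 1)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$conf_low, -r3$conf_high)

  expect_error(t_test_summary(5, 1, 0, 5, 1, 0),
               class = "metscore_degenerate_input")
  expect_error(t_test_summary(1, 1, 1, 5, 1, 1),
               class = "metscore_insufficient_data")
})

test_that("raw-data t-test equals the summary route exactly and matches stats::t.test", {
  withr::with_seed(12, {
    for (i in 1:5) {
      x <- rnorm(30 + i, 0.3)
      y <- rnorm(50 - i)
      ours <- t_test_raw(x, y)
      via_summary <- t_test_summary(length(x), mean(x), sd(x),
                                    length(y), mean(y), sd(y))
      expect_equal(ours, via_summary, tolerance = 1e-12)
      ref <- t.test(x, y, var.equal = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(c(ours$conf_low, ours$conf_high),
                   as.numeric(ref$conf.int), tolerance = 1e-12)
      refw <- t.test(x, y)
      welch <- t_test_raw(x, y, var_equal = FALSE)
      expect_equal(welch$p_value, refw$p.value, tolerance = 1e-12)
      expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-10)
    }
  })
})

test_that("a constructed one-unit shift is estimated at minus one", {
  fx <- shift_fixture(n = 100, shift = 1)
  r <- t_test_raw(fx$g1, fx$g2)
  expect_equal(r$estimate, -1, tolerance = 1e-12)  # deterministic fixture
  expect_lt(r$p_value, 1e-10)
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small groups", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  withr::with_seed(314, {
    sizes <- list(c(3, 3), c(4, 5), c(2, 8), c(6, 6), c(8, 8))
    for (sz in sizes) {
      x <- rnorm(sz[1])
      y <- rnorm(sz[2], 0.8)
      expect_equal(mann_whitney(x, y)$p_value, mw_exact_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
  # identical multisets: tied, normal approximation, p near 1
  same <- c(1, 2, 3, 4, 5)
  expect_gt(mann_whitney(same, same)$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "metscore_insufficient_data")
})

test_that("Bonferroni correction caps at one and is monotone", {
  expect_equal(round(bonferroni(0.000491114, 37), 3), 0.018)
  expect_equal(bonferroni(0.5, 37), 1)
  p <- c(0.001, 0.04, 0.9)
  expect_equal(bonferroni(p, 1), p)
  expect_true(all(bonferroni(p, 5) >= p))
  expect_true(all(diff(bonferroni(sort(runif(10)), 7)) >= 0))
  expect_error(bonferroni(1.5), class = "metscore_parameter_error")
})

test_that("per-trait association dispatches on the normality screen", {
  withr::with_seed(6, {
    carrier <- rep(c(FALSE, TRUE), each = 60)
    normal_vals <- rnorm(120)
    heavy_vals <- rcauchy(120)
  })
  # tight alpha separates the dispatch mechanism from the screen's 5% level
  expect_identical(
    per_trait_association(normal_vals, carrier, alpha = 1e-4)$test_used, "t")
  expect_identical(
    per_trait_association(heavy_vals, carrier, alpha = 1e-4)$test_used,
    "mann_whitney")
})

test_that("2x2 chi-square matches the direct O-E formula and flags zero margins", {
  g <- rep(c("a", "b"), each = 40)
  s <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(30, 10, 10, 30))
  r <- chi2_association(g, s)
  O <- matrix(c(30, 10, 10, 30), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(r$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_equal(r$df, 1)

  bal <- chi2_association(rep(c("a", "b"), each = 100),
                          rep(c(TRUE, FALSE), times = 100))
  expect_equal(bal$statistic, 0, tolerance = 1e-12)
  expect_equal(bal$p_value, 1, tolerance = 1e-12)

  expect_error(chi2_association(rep("a", 10), rep(c(TRUE, FALSE), 5)),
               class = "metscore_parameter_error")
  expect_error(chi2_association(rep(c("a", "b"), each = 5), rep(TRUE, 10)),
               class = "metscore_parameter_error")
})

test_that("chi-square association holds its level on null tables", {
  withr::with_seed(321, {
    hits <- vapply(seq_len(600), function(i) {
      g <- rbinom(206, 1, 0.4)
      s <- rbinom(206, 1, 0.46)
      chi2_association(g, s)$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("risk-genotype counting honors per-SNP orientation and missingness", {
  geno <- tibble::tibble(id = c("a", "b", "c"),
                         rs1 = c(0L, 1L, 2L),
                         rs2 = c(0L, 0L, 1L),
                         rs3 = c(2L, NA, 0L),
                         rs4 = c(0L, 0L, 0L))
  panel <- tibble::tibble(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                          risk = c("carrier", "carrier", "carrier",
                                   "noncarrier"))
  rc <- risk_genotype_count(geno, panel)
  expect_identical(rc$risk_count, c(2L, NA, 3L))
  # protective-allele orientation: NON-carriers of rs1 are the risk group
  flip <- panel
  flip$risk[1] <- "noncarrier"
  expect_identical(risk_genotype_count(geno, flip)$risk_count[1], 3L)
  # all-zero dosages under carrier orientation count zero
  zero <- tibble::tibble(id = "z", rs1 = 0L, rs2 = 0L, rs3 = 0L, rs4 = 0L)
  expect_identical(
    risk_genotype_count(zero, dplyr::mutate(panel, risk = "carrier"))$risk_count,
    0L)
  expect_error(risk_genotype_count(geno, tibble::tibble(snp_id = "rsX",
                                                        risk = "carrier")),
               class = "metscore_schema_error")
})

test_that("minimum detectable difference matches the normal closed form", {
  expect_equal(round(min_detectable_diff(156, 50, sd = 1.41), 3), 0.642)
  expect_equal(round(min_detectable_diff(58, 148, sd = 1.41), 3), 0.612)
  expect_equal(round(min_detectable_diff(192, 13, sd = 1.41), 3), 1.132)
  # linear in sigma
  expect_equal(min_detectable_diff(50, 50, sd = 2.82),
               2 * min_detectable_diff(50, 50, sd = 1.41), tolerance = 1e-12)
  # inverse consistency with the power formula
  d <- min_detectable_diff(156, 50, sd = 1.41, power = 0.8)
  expect_equal(power_two_sample(d, 156, 50, sd = 1.41), 0.8, tolerance = 1e-6)
  # noncentral-t refinement: slightly larger, and achieves the target power
  dt <- min_detectable_diff(156, 50, sd = 1.41, method = "noncentral_t")
  expect_gt(dt, d)
  se <- 1.41 * sqrt(1 / 156 + 1 / 50)
  tc <- qt(0.975, 204)
  achieved <- pt(tc, 204, ncp = dt / se, lower.tail = FALSE) +
    pt(-tc, 204, ncp = dt / se)
  expect_equal(achieved, 0.8, tolerance = 1e-8)
  expect_error(min_detectable_diff(1, 50), class = "metscore_parameter_error")
})

test_that("cohort-level association table handles degenerate SNPs and defaults m", {
  coh <- generate_cohort(synthetic_config(n = 300, seed = 47))
  m <- fit_mets_score(coh$phenotypes)
  sc <- compute_scores(m, coh$phenotypes)
  geno <- dplyr::mutate(coh$genotypes, rs_mono = 0L)
  res <- associate_snps(sc, geno)
  expect_identical(res$m[1], ncol(geno) - 1L)
  mono <- dplyr::filter(res, snp_id == "rs_mono")
  expect_identical(mono$note, "skipped")
  expect_true(is.na(mono$p_value))
  ok <- dplyr::filter(res, note == "")
  expect_true(all(ok$p_bonferroni >= ok$p_value))
  expect_true(all(ok$n1 + ok$n2 <= 300))
})

test_that("per-SNP HWE report mirrors the descriptive table layout", {
  coh <- generate_cohort(synthetic_config(n = 400, seed = 53))
  geno <- dplyr::mutate(coh$genotypes, rs_mono = 0L)
  rep <- hwe_report(geno)
  expect_identical(nrow(rep), ncol(geno) - 1L)
  expect_identical(rep$note[rep$snp_id == "rs_mono"], "monomorphic")
  ok <- dplyr::filter(rep, note == "")
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
  expect_true(all(abs(ok$maf - (ok$n_het + 2 * ok$n_hom_minor) / (2 * ok$n))
                  < 1e-12))
})
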