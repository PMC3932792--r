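# SNP-level descriptives (MAF, Hardy-Weinberg), dominance-model association
# of candidate SNPs with the continuous MetS score, multiple-testing
# correction, risk-genotype counting, and minimum-detectable-difference
# power analysis.  The two-sample arithmetic is written out explicitly so
# that published summary statistics (n, mean, SD per genotype group) can be
# fed in directly, without individual-level data.

#' Minor allele frequency from a dosage vector
#'
#' @param dosages Integer vector in `{0, 1, 2}` counting minor alleles;
#'   missing values are excluded (pairwise deletion, so sample size may vary
#'   across SNPs).
#' @return Allele frequency `sum(dosages) / (2 * n_nonmissing)`.
#' @export
#' @examples
#' maf(c(0, 0, 1, 2)) # 3/8
maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) abort("All dosages missing.", class = "metscore_insufficient_data")
  if (any(!d %in% 0:2)) abort("Dosages must be 0, 1 or 2.",
                              class = "metscore_parameter_error")
  sum(d) / (2 * length(d))
}

#' Hardy-Weinberg equilibrium chi-square test from genotype counts
#'
#' Pearson chi-square on one degree of freedom comparing observed genotype
#' counts with the Hardy-Weinberg expectations `n(1-q)^2, 2nq(1-q), nq^2`
#' computed at the observed allele frequency `q`; no continuity correction.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts.
#' @return One-row tibble: counts, `n`, `maf`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: chi-square 0
hwe_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("Genotype counts must be non-negative with total >= 1.",
          class = "metscore_parameter_error")
  }
  n <- sum(counts)
  q <- (n_het + 2 * n_hom_minor) / (2 * n)
  if (q == 0 || q == 1) {
    abort("Monomorphic SNP: HWE test undefined.",
          class = "metscore_degenerate_input")
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((counts - expected)^2 / expected)
  tibble::tibble(n_hom_major = n_hom_major, n_het = n_het,
                 n_hom_minor = n_hom_minor, n = n, maf = q,
                 statistic = stat, df = 1,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Dominance-model grouping of a dosage vector
#'
#' Splits individuals into major-allele homozygotes (reference) and carriers
#' of at least one minor allele, the contrast used throughout the
#' association analysis.  Missing dosages fall in neither group.
#'
#' @inheritParams maf
#' @return List with integer index vectors `reference` (dosage 0) and
#'   `carrier` (dosage >= 1).
#' @export
group_dominant <- function(dosages) {
  list(reference = which(!is.na(dosages) & dosages == 0),
       carrier = which(!is.na(dosages) & dosages >= 1))
}

#' Pooled two-sample t-test from group summary statistics
#'
#' Student t-test with pooled variance, computed from per-group n, mean and
#' SD — exactly the arithmetic needed to re-derive a published association
#' table from its printed summaries.  The mean difference is reported as
#' `mean1 - mean2`.
#'
#' @param n1,mean1,sd1 Reference-group summaries (n >= 2).
#' @param n2,mean2,sd2 Comparison-group summaries.
#' @param level Confidence level for the interval (default 0.95).
#' @param var_equal Pooled variance (default TRUE); `FALSE` gives the Welch
#'   test with Satterthwaite degrees of freedom.
#' @return One-row tibble: group summaries, `estimate` (mean1 - mean2),
#'   `conf_low`, `conf_high`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' # published genotype-group summaries reproduce the printed test
#' t_test_summary(156, 0.192, 1.380, 50, -0.600, 1.362)
t_test_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                           level = 0.95, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) abort("Each group needs n >= 2.",
                              class = "metscore_insufficient_data")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    abort("SDs must be non-negative and not both zero.",
          class = "metscore_degenerate_input")
  }
  diff <- mean1 - mean2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- diff / se
  tcrit <- qt((1 + level) / 2, df)
  tibble::tibble(n1 = n1, mean1 = mean1, sd1 = sd1,
                 n2 = n2, mean2 = mean2, sd2 = sd2,
                 estimate = diff, conf_low = diff - tcrit * se,
                 conf_high = diff + tcrit * se,
                 statistic = stat, df = df,
                 p_value = 2 * pt(-abs(stat), df), level = level)
}

#' Two-sample t-test on raw values
#'
#' Computes each group's n, mean and SD and delegates to
#' [t_test_summary()], so raw-data and summary-statistic routes agree
#' exactly.
#'
#' @param values1,values2 Numeric vectors (missing values dropped; at least
#'   2 per group).
#' @inheritParams t_test_summary
#' @return As [t_test_summary()].
#' @export
t_test_raw <- function(values1, values2, level = 0.95, var_equal = TRUE) {
  x <- values1[!is.na(values1)]
  y <- values2[!is.na(values2)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 non-missing values.",
          class = "metscore_insufficient_data")
  }
  t_test_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y),
                 level = level, var_equal = var_equal)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration for small
#' tie-free samples, otherwise the normal approximation with midranks and
#' tie correction.
#'
#' @param values1,values2 Numeric vectors, at least one value each.
#' @return One-row tibble: `statistic` (U for the first group), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(values1, values2) {
  x <- values1[!is.na(values1)]
  y <- values2[!is.na(values2)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both groups need at least one value.",
          class = "metscore_insufficient_data")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal")
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each raw p-value.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Number of tests in the family (default 37, the size of the
#'   candidate-SNP panel this package ships).
#' @return Corrected p-value(s).
#' @export
bonferroni <- function(p_raw, m = 37) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE) || m < 1) {
    abort("Need 0 <= p_raw <= 1 and m >= 1.", class = "metscore_parameter_error")
  }
  pmin(1, m * p_raw)
}

#' Normality-dispatched two-group comparison of a quantitative trait
#'
#' Runs [t_test_raw()] when both groups pass the Shapiro-Wilk screen at
#' `alpha`, otherwise [mann_whitney()]; records which test ran.  Used for
#' the per-trait SNP association analysis.
#'
#' @param values Numeric trait values.
#' @param carrier Logical dominance-grouping indicator (TRUE = carrier);
#'   missing excluded.
#' @param alpha Normality-screen level (default 0.05).
#' @return One-row tibble: `test_used`, `statistic`, `p_value`, group sizes.
#' @export
per_trait_association <- function(values, carrier, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(carrier)
  x <- values[keep & !carrier]
  y <- values[keep & carrier]
  normal <- tryCatch(
    shapiro_normality(x)$p_value >= alpha && shapiro_normality(y)$p_value >= alpha,
    error = function(e) FALSE)
  if (normal) {
    res <- t_test_raw(x, y)
    tibble::tibble(test_used = "t", statistic = res$statistic,
                   p_value = res$p_value, n_ref = length(x), n_carrier = length(y))
  } else {
    res <- mann_whitney(x, y)
    tibble::tibble(test_used = "mann_whitney", statistic = res$statistic,
                   p_value = res$p_value, n_ref = length(x), n_carrier = length(y))
  }
}

#' Chi-square test of association for a 2x2 table
#'
#' Pearson chi-square on 1 df, without continuity correction by default,
#' for genotype-group versus binary-status contrasts and other proportion
#' comparisons.
#'
#' @param group,status Parallel vectors coercible to 2-level factors.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi2_association <- function(group, status, correct = FALSE) {
  keep <- !is.na(group) & !is.na(status)
  tab <- table(factor(group[keep]), factor(status[keep]))
  if (any(dim(tab) != 2)) {
    abort("Need exactly two levels in each margin.",
          class = "metscore_parameter_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Zero margin in the 2x2 table; consider an exact test.",
          class = "metscore_degenerate_input")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Per-individual count of risk genotypes across a SNP panel
#'
#' Tallies, for each individual, how many SNPs show the risk-oriented
#' genotype under the dominance model.  Orientation must be explicit per
#' SNP because the risk direction can flip: for a protective minor allele
#' the risk state is NON-carrier.
#'
#' @param genotypes Data frame with `id` and one dosage column per SNP.
#' @param risk_snps Tibble with columns `snp_id` and `risk`
#'   (`"carrier"` or `"noncarrier"`).
#' @return Tibble `id`, `risk_count`; a missing dosage at any panel SNP
#'   makes that individual's count missing.
#' @export
risk_genotype_count <- function(genotypes, risk_snps) {
  if (!all(c("snp_id", "risk") %in% names(risk_snps))) {
    abort("`risk_snps` needs columns snp_id and risk.",
          class = "metscore_parameter_error")
  }
  unknown <- setdiff(risk_snps$snp_id, names(genotypes))
  if (length(unknown) > 0) {
    abort(paste0("SNP(s) not in genotype table: ", paste(unknown, collapse = ", ")),
          class = "metscore_schema_error")
  }
  bad <- setdiff(risk_snps$risk, c("carrier", "noncarrier"))
  if (length(bad) > 0) {
    abort(paste0("Unknown risk orientation: ", paste(bad, collapse = ", ")),
          class = "metscore_parameter_error")
  }
  risk_mat <- vapply(seq_len(nrow(risk_snps)), function(i) {
    d <- genotypes[[risk_snps$snp_id[i]]]
    if (risk_snps$risk[i] == "carrier") as.numeric(d >= 1) else as.numeric(d == 0)
  }, numeric(nrow(genotypes)))
  risk_mat <- matrix(risk_mat, nrow = nrow(genotypes))
  tibble::tibble(id = genotypes$id, risk_count = as.integer(rowSums(risk_mat)))
}

#' Minimum detectable mean difference of a two-sample design
#'
#' Normal-approximation solution
#' `delta = (z_{1-alpha/2} + z_{power}) * sd * sqrt(1/n1 + 1/n2)`;
#' `method = "noncentral_t"` refines it by solving the exact noncentral-t
#' power equation of the pooled test.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param sd Common outcome SD (default 1.41, a typical dispersion for a
#'   two-component equally weighted PCA score).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @param method `"normal"` (default) or `"noncentral_t"`.
#' @return The detectable difference, in outcome units.
#' @export
#' @examples
#' min_detectable_diff(156, 50, sd = 1.41)
min_detectable_diff <- function(n1, n2, sd = 1.41, alpha = 0.05, power = 0.80,
                                method = c("normal", "noncentral_t")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2 || sd <= 0 || alpha <= 0 || alpha >= 1 ||
      power <= 0 || power >= 1) {
    abort("Invalid power specification.", class = "metscore_parameter_error")
  }
  se <- sd * sqrt(1 / n1 + 1 / n2)
  delta0 <- (qnorm(1 - alpha / 2) + qnorm(power)) * se
  if (method == "normal") return(delta0)
  df <- n1 + n2 - 2
  tcrit <- qt(1 - alpha / 2, df)
  pw <- function(delta) {
    ncp <- delta / se
    pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      pt(-tcrit, df, ncp = ncp) - power
  }
  stats::uniroot(pw, lower = delta0 / 2, upper = delta0 * 3, tol = 1e-10)$root
}

#' Achieved power for a given mean difference (normal approximation)
#'
#' Inverse companion of [min_detectable_diff()]:
#' `power = Phi(delta / (sd * sqrt(1/n1 + 1/n2)) - z_{1-alpha/2})`.
#'
#' @param delta Mean difference to detect.
#' @inheritParams min_detectable_diff
#' @return Power in `(0, 1)`.
#' @export
power_two_sample <- function(delta, n1, n2, sd = 1.41, alpha = 0.05) {
  se <- sd * sqrt(1 / n1 + 1 / n2)
  pnorm(abs(delta) / se - qnorm(1 - alpha / 2))
}

#' Per-SNP HWE and MAF report
#'
#' @param genotypes Data frame with `id` and one dosage column per SNP.
#' @return Tibble with one row per SNP: genotype counts, `n`, `maf`, HWE
#'   `statistic` and `p_value` (missing, with a note, for monomorphic SNPs).
#' @export
hwe_report <- function(genotypes) {
  snps <- setdiff(names(genotypes), "id")
  purrr::map_dfr(snps, function(s) {
    d <- genotypes[[s]]
    d <- d[!is.na(d)]
    counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    res <- tryCatch(hwe_test(counts[1], counts[2], counts[3]),
      metscore_degenerate_input = function(e) {
        tibble::tibble(n_hom_major = counts[1], n_het = counts[2],
                       n_hom_minor = counts[3], n = sum(counts),
                       maf = (counts[2] + 2 * counts[3]) / (2 * sum(counts)),
                       statistic = NA_real_, df = 1, p_value = NA_real_)
      })
    tibble::add_column(res, snp_id = s, .before = 1) |>
      dplyr::mutate(note = ifelse(is.na(.data$statistic), "monomorphic", ""))
  })
}

#' Dominance-model association of every SNP with the MetS score
#'
#' For each SNP, contrasts major-allele homozygotes against carriers with a
#' pooled two-sample t-test on the continuous score and applies the
#' Bonferroni correction.  SNPs with an empty group (or fewer than 2 in
#' either) are reported as skipped rather than failing the run.
#'
#' @param scores Data frame with `id` and `score` (e.g. from
#'   [compute_scores()]).
#' @param genotypes Data frame with `id` and one dosage column per SNP;
#'   aligned to `scores` by `id`.
#' @param m Bonferroni family size; defaults to the number of SNPs tested.
#' @param level Confidence level (default 0.95).
#' @param var_equal Pooled (TRUE, default) or Welch test.
#' @return Tibble, one row per SNP: group sizes/means/SDs, `estimate`
#'   (reference minus carrier), CI, `statistic`, `df`, `p_value`,
#'   `p_bonferroni`, `m`, `maf`, `note` (`"skipped"` when degenerate).
#' @export
associate_snps <- function(scores, genotypes, m = NULL, level = 0.95,
                           var_equal = TRUE) {
  merged <- dplyr::inner_join(tibble::as_tibble(scores),
                              tibble::as_tibble(genotypes), by = "id")
  if (nrow(merged) == 0) {
    abort("No overlapping ids between scores and genotypes.",
          class = "metscore_alignment_error")
  }
  snps <- setdiff(names(genotypes), "id")
  m <- m %||% length(snps)
  res <- purrr::map_dfr(snps, function(s) {
    d <- merged[[s]]
    grp <- group_dominant(d)
    base <- tibble::tibble(snp_id = s,
                           maf = tryCatch(maf(d), error = function(e) NA_real_))
    if (length(grp$reference) < 2 || length(grp$carrier) < 2) {
      return(dplyr::mutate(base, n1 = length(grp$reference),
                           n2 = length(grp$carrier), estimate = NA_real_,
                           p_value = NA_real_, note = "skipped"))
    }
    tt <- t_test_raw(merged$score[grp$reference], merged$score[grp$carrier],
                     level = level, var_equal = var_equal)
    dplyr::bind_cols(base, tt) |> dplyr::mutate(note = "")
  })
  res$m <- m
  res$p_bonferroni <- bonferroni(res$p_value, m)
  res
}
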