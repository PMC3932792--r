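# Shared fixtures and independent oracles used across test files.

# One-SNP panel for fast null simulations.
one_snp_panel <- function(maf = 0.3) {
  tibble::tibble(gene = "GENE1", snp_id = "rs0001", maf = maf)
}

# Population explained-variance proportion of the top-k principal components
# of the generator's correlation matrix (independent oracle: closed form
# from the configured loadings/uniqueness, no sampling).
population_explained <- function(loadings, k = 2) {
  psi <- 1 - rowSums(loadings^2)
  R <- loadings %*% t(loadings) + diag(psi)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  sum(ev[seq_len(k)]) / nrow(loadings)
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value:
# enumerates every assignment of the pooled tie-free values to group 1.
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Deterministic two-group fixture with a known shift.
shift_fixture <- function(n = 100, shift = 1) {
  base <- qnorm(seq_len(n) / (n + 1))  # deterministic normal scores
  list(g1 = base, g2 = base + shift)
}

# Minimal valid phenotype row, overridable per field.
phenotype_row <- function(...) {
  row <- tibble::tibble(
    id = "P1", waist_cm = 90, dbp_mmHg = 75, sbp_mmHg = 120,
    glucose_mg_dl = 90, hdl_mg_dl = 55, tg_mg_dl = 100,
    sex = "male", age_years = 50, smoker = FALSE, excess_alcohol = FALSE,
    inactive = FALSE, unhealthy_diet = FALSE, med_htn = FALSE,
    med_chol = FALSE, med_diab = FALSE)
  args <- list(...)
  for (nm in names(args)) row[[nm]] <- args[[nm]]
  row
}
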