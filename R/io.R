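# File input/output and the end-to-end pipeline runner.

sniff_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a phenotype table from CSV/TSV
#'
#' Expects the documented header (`id`, the six [mets_traits()] columns,
#' `sex`, `age_years` and the seven logical flags); the delimiter is
#' sniffed from the first line.  Units follow the column names (cm, mmHg,
#' mg/dL).  Missing values are retained; non-positive traits are a
#' validation error naming the offending records.
#'
#' @param path File path.
#' @return Typed tibble in the standard column layout.
#' @export
read_phenotypes <- function(path) {
  delim <- sniff_delim(path)
  flags <- c("smoker", "excess_alcohol", "inactive", "unhealthy_diet",
             "med_htn", "med_chol", "med_diab")
  spec <- do.call(readr::cols, c(
    list(id = readr::col_character(), sex = readr::col_character(),
         age_years = readr::col_double()),
    setNames(rep(list(readr::col_double()), 6), mets_traits()),
    setNames(rep(list(readr::col_logical()), length(flags)), flags)))
  # missing-column complaints surface as a schema error below, not a warning
  dat <- suppressWarnings(readr::read_delim(path, delim = delim,
                                            col_types = spec, na = c("", "NA")))
  prob <- readr::problems(dat)
  if (nrow(prob) > 0) {
    abort(paste0("Unparseable value(s) at line(s): ",
                 paste(utils::head(unique(prob$row), 10), collapse = ", ")),
          class = "metscore_parse_error")
  }
  missing_cols <- setdiff(phenotype_columns(), names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "metscore_schema_error")
  }
  for (tr in mets_traits()) {
    bad <- !is.na(dat[[tr]]) & dat[[tr]] <= 0
    if (any(bad)) {
      abort(paste0("Non-positive ", tr, " for record(s): ",
                   paste(utils::head(dat$id[bad], 10), collapse = ", ")),
            class = "metscore_validation_error")
    }
  }
  bad_sex <- !is.na(dat$sex) & !dat$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(paste0("sex must be 'male' or 'female'; offending record(s): ",
                 paste(utils::head(dat$id[bad_sex], 10), collapse = ", ")),
          class = "metscore_validation_error")
  }
  dat[phenotype_columns()]
}

#' Read a genotype matrix from CSV or VCF
#'
#' CSV: an `id` column plus one column per SNP holding minor-allele dosages
#' 0/1/2 (or NA).  VCF (via \pkg{vcfR}): biallelic sites only — multiallelic
#' records are skipped with a warning — with dosages counted on the minor
#' allele within the loaded sample by default, or on the ALT allele with
#' `orient = "alt"` to keep orientation stable across cohorts.  The
#' orientation actually used per SNP is recorded in the `"snp_info"`
#' attribute.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"vcf"`.
#' @param orient For VCF input: count the within-sample `"minor"` allele
#'   (default) or always the `"alt"` allele.
#' @return Tibble `id` + one integer dosage column per SNP, with attribute
#'   `"snp_info"` (snp_id, and for VCF ref/alt, counted allele, maf).
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"),
                           orient = c("minor", "alt")) {
  format <- match.arg(format)
  orient <- match.arg(orient)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  if (format == "csv") {
    dat <- readr::read_delim(path, delim = sniff_delim(path),
                             col_types = readr::cols(
                               id = readr::col_character(),
                               .default = readr::col_integer()),
                             na = c("", "NA"))
    snps <- setdiff(names(dat), "id")
    for (s in snps) {
      if (any(!is.na(dat[[s]]) & !dat[[s]] %in% 0:2)) {
        abort(paste0("Dosages for ", s, " must be 0, 1, 2 or NA."),
              class = "metscore_validation_error")
      }
    }
    attr(dat, "snp_info") <- tibble::tibble(
      snp_id = snps,
      maf = vapply(snps, function(s)
        tryCatch(maf(dat[[s]]), error = function(e) NA_real_), numeric(1)))
    return(dat)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warn(paste0("Skipping ", sum(!bi), " multiallelic VCF record(s)."))
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- colnames(gt)
  snp_ids <- vcf@fix[, "ID"]
  snp_ids[is.na(snp_ids) | snp_ids == "."] <-
    paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"])[is.na(snp_ids) | snp_ids == "."]
  alt_dosage <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE),
                  function(a) sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 1, alt_dosage)       # samples x snps
  dos <- matrix(as.integer(dos), nrow = length(ids),
                dimnames = list(NULL, snp_ids))
  counted <- rep("ALT", ncol(dos))
  if (orient == "minor") {
    for (j in seq_len(ncol(dos))) {
      af <- mean(dos[, j], na.rm = TRUE) / 2
      if (!is.nan(af) && af > 0.5) {
        dos[, j] <- 2L - dos[, j]
        counted[j] <- "REF"
      }
    }
  }
  out <- tibble::as_tibble(dos)
  out <- tibble::add_column(out, id = ids, .before = 1)
  attr(out, "snp_info") <- tibble::tibble(
    snp_id = snp_ids, ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
    counted_allele = counted,
    maf = vapply(seq_len(ncol(dos)), function(j)
      tryCatch(maf(dos[, j]), error = function(e) NA_real_), numeric(1)))
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in analysis order — normalize, score, classify,
#' HWE/MAF, associate, correct, risk-count trend, adjust, power — and writes
#' one TSV per report plus a plain-text run log.  Deterministic given the
#' inputs and seed.
#'
#' @param phenotypes Phenotype tibble or a path readable by
#'   [read_phenotypes()].
#' @param genotypes Genotype tibble or a path readable by
#'   [read_genotypes()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param transforms,weighting Passed to [fit_mets_score()].
#' @param m Bonferroni family size (default: number of SNPs tested).
#' @param level Confidence level for intervals.
#' @param alpha,power Passed to [min_detectable_diff()].
#' @param covariates Candidate covariates for the adjusted model.
#' @param risk_snps Optional tibble (`snp_id`, `risk`) for the genetic
#'   risk-count trend stage; `NULL` skips it.
#' @param seed Optional integer seed (the analysis itself is deterministic;
#'   the seed is recorded and set for reproducibility of any downstream
#'   resampling a caller adds).
#' @return List of class `mets_pipeline`: `model`, `scores`, `status`,
#'   `prevalence`, `validation`, `hwe`, `association`, `adjusted` (screen +
#'   results), `risk_trend` (or NULL), `power`.
#' @export
run_pipeline <- function(phenotypes, genotypes, out_dir = NULL,
                         transforms = "fixed", weighting = "proportional",
                         m = NULL, level = 0.95, alpha = 0.05, power = 0.80,
                         covariates = c("age_years", "sex", "smoker",
                                        "excess_alcohol", "inactive",
                                        "unhealthy_diet"),
                         risk_snps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage <- "read inputs"
  result <- tryCatch({
    if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
    if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
    common <- intersect(phenotypes$id, genotypes$id)
    if (length(common) == 0) {
      abort(paste0("No common ids (", nrow(phenotypes), " phenotype vs ",
                   nrow(genotypes), " genotype records)."),
            class = "metscore_alignment_error")
    }
    phenotypes <- dplyr::filter(phenotypes, .data$id %in% common)
    genotypes <- dplyr::filter(genotypes, .data$id %in% common)

    stage <- "score model"
    model <- fit_mets_score(phenotypes, transforms = transforms,
                            weighting = weighting)
    cc <- complete.cases(phenotypes[mets_traits()])
    scored <- phenotypes[cc, ]
    scores <- compute_scores(model, scored)

    stage <- "classification"
    status <- classify_mets(scored)
    prevalence <- mets_prevalence(status)
    validation <- validate_score(scores$score, status$mets, status$risk_count)

    stage <- "HWE/MAF"
    hwe <- hwe_report(genotypes)

    stage <- "association"
    association <- associate_snps(scores, genotypes, m = m, level = level)

    stage <- "risk-count trend"
    risk_trend <- NULL
    if (!is.null(risk_snps)) {
      counts <- risk_genotype_count(genotypes, risk_snps)
      joined <- dplyr::inner_join(scores, counts, by = "id")
      risk_trend <- list(counts = counts,
                         trend = anova_trend(joined$score, joined$risk_count))
    }

    stage <- "adjusted model"
    adjusted <- associate_snps_adjusted(scores, genotypes, scored,
                                        covariates = covariates)

    stage <- "power"
    sd_score <- sd(scores$score)
    pw <- association |>
      dplyr::filter(.data$note == "") |>
      dplyr::mutate(min_detectable = purrr::map2_dbl(
        .data$n1, .data$n2,
        ~ min_detectable_diff(.x, .y, sd = sd_score, alpha = alpha,
                              power = power))) |>
      dplyr::select("snp_id", "n1", "n2", "min_detectable")
    structure(
      list(model = model, scores = scores, status = status,
           prevalence = prevalence, validation = validation, hwe = hwe,
           association = association, adjusted = adjusted,
           risk_trend = risk_trend,
           power = list(sd = sd_score, alpha = alpha, power = power,
                        table = pw)),
      class = "mets_pipeline")
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(e),
                 "  (Check the inputs this stage consumes.)"),
          class = "metscore_pipeline_error", parent = e)
  })
  if (!is.null(out_dir)) write_pipeline(result, out_dir, seed = seed)
  result
}

write_pipeline <- function(result, out_dir, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(result$scores, file.path(out_dir, "scores.tsv"))
  readr::write_tsv(result$status, file.path(out_dir, "status.tsv"))
  readr::write_tsv(result$hwe, file.path(out_dir, "hwe_maf.tsv"))
  readr::write_tsv(result$association, file.path(out_dir, "association.tsv"))
  readr::write_tsv(result$adjusted$screen, file.path(out_dir, "screening.tsv"))
  readr::write_tsv(result$adjusted$results, file.path(out_dir, "adjusted.tsv"))
  readr::write_tsv(result$power$table, file.path(out_dir, "power.tsv"))
  write_score_model(result$model, file.path(out_dir, "score_model.txt"))
  log_lines <- c(
    paste0("metscore ", as.character(utils::packageVersion("metscore"))),
    paste0("R ", R.version.string),
    paste0("timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed ", seed %||% "none"),
    paste0("n_scored ", nrow(result$scores)),
    paste0("weighting ", result$model$weighting),
    paste0("transforms ", paste0(result$model$transform_spec$trait, "=",
                                 result$model$transform_spec$transform,
                                 collapse = ",")),
    paste0("bonferroni_m ", result$association$m[1]),
    paste0("prevalence ", sprintf("%.4f", result$prevalence$p_hat)))
  readr::write_lines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.mets_pipeline <- function(x, ...) {
  cat("MetS pipeline on", nrow(x$scores), "scored individuals\n")
  cat(sprintf("Prevalence: %.2f%% (%.2f-%.2f%%)\n",
              100 * x$prevalence$p_hat, 100 * x$prevalence$conf_low,
              100 * x$prevalence$conf_high))
  sig <- dplyr::filter(x$association, !is.na(.data$p_value), .data$p_value < 0.05)
  cat(nrow(sig), "SNP(s) associated at raw p < 0.05 of",
      nrow(x$association), "tested\n")
  invisible(x)
}
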