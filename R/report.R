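# stable polynomial hash (mod 2^31 - 1) of a configuration's JSON
# serialization, for run metadata
.config_hash <- function(x) {
  s <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.adjust_vars <- c("age", "psa_log", "pgg", "tumor_vol_num", "pni", "lvi",
                  "am", "bm", "cm", "vm", "lnm")

# derived modelling columns shared by the table builders
.prepare_model_frame <- function(staged) {
  staged$psa_log <- log(staged$psa)
  staged$tumor_vol_num <- match(staged$tumor_vol_group, c("<=2", "2-5", ">5"))
  staged$radial_high <- as.integer(staged$radial_mm > 0.75)
  staged$area_high <- as.integer(staged$area_mm2 > 2)
  staged$multifocal <- as.integer(staged$n_epe > 1)
  staged$psa_high <- as.integer(staged$psa > stats::median(staged$psa))
  staged$age_high <- as.integer(staged$age > stats::median(staged$age))
  staged
}

#' Run the full substaging analysis on a cohort
#'
#' Orchestrates the end-to-end analysis of a pT3a cohort table: staging
#' layer, demographics comparison by recurrence status, Cox regression of
#' the three EPE parameters (radial distance over 0.75 mm, 2D square area
#' over 2 mm2, more than one focus; unadjusted and covariate-adjusted),
#' the combined (radial bin, focus number) Cox model, univariable and
#' multivariable recurrence models, and Kaplan-Meier curves by substage
#' and by CM-merged group. The report is deterministic given the input.
#'
#' @param cohort an `epe_cohort` from [generate_cohort()] or a patient
#'   `data.frame` with the generator's column dictionary (at minimum
#'   `radial_mm`, `n_epe`, `time`, `bcr_event`; covariate columns enable
#'   the corresponding tables).
#' @param adjust covariate names used in adjusted models (defaults to the
#'   full clinicopathologic set).
#' @return An object of class `analysis_report`: list with `demographics`,
#'   `epe_cox` (per-parameter unadjusted/adjusted HRs), `combined_bin`
#'   (seven-group model table), `uni_multi` (univariable + multivariable
#'   table), `km_substage`, `km_cm` (when CM present), and `metadata`.
#' @examples
#' rep <- run_analysis(generate_cohort(cohort_config(n_patients = 200)))
#' rep$combined_bin
#' @export
run_analysis <- function(cohort, adjust = .adjust_vars) {
  patients <- if (inherits(cohort, "epe_cohort")) cohort$patients else cohort
  req <- c("radial_mm", "n_epe", "time", "bcr_event")
  miss <- setdiff(req, names(patients))
  if (length(miss))
    stop("validation error: missing columns: ", paste(miss, collapse = ", "))
  staged <- stage_cohort(patients)
  staged <- .prepare_model_frame(staged)
  adjust <- intersect(adjust, names(staged))

  demo <- .demographics_table(staged)
  epe_cox <- .epe_parameter_table(staged, adjust)
  fit3 <- fit_cox(survival::Surv(time, bcr_event) ~ group, staged)
  combined_bin <- rbind(
    data.frame(term = "groupr1_n1 (ref)", hr = 1, ci_lower = NA_real_,
               ci_upper = NA_real_, p_value = NA_real_,
               c_index = fit3$c_index, stringsAsFactors = FALSE),
    cox_table(fit3))
  uni_multi <- .uni_multi_table(staged)
  km_sub <- km_estimate(staged$time, staged$bcr_event, staged$substage)
  km_cm <- if ("cm_merged_group" %in% names(staged))
    km_estimate(staged$time, staged$bcr_event, staged$cm_merged_group)
  else NULL

  cfg <- if (inherits(cohort, "epe_cohort")) cohort$config else NULL
  structure(list(
    demographics = demo,
    epe_cox = epe_cox,
    combined_bin = combined_bin,
    combined_bin_fit = fit3,
    uni_multi = uni_multi,
    km_substage = km_sub,
    km_cm = km_cm,
    metadata = list(
      n = nrow(staged), n_events = sum(staged$bcr_event),
      seed = cfg$seed %||% NA,
      config_hash = if (is.null(cfg)) NA_character_ else .config_hash(cfg),
      package_version = as.character(utils::packageVersion("epestage")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("pT3a substaging analysis report: n =", x$metadata$n,
      ", events =", x$metadata$n_events, "\n")
  cat("combined-bin model (reference r1_n1):\n")
  print(cbind(x$combined_bin[1], round(x$combined_bin[-1], 3)))
  if (!is.null(x$km_substage$logrank_p))
    cat("log-rank across substages: p =",
        signif(x$km_substage$logrank_p, 3), "\n")
  invisible(x)
}

.demographics_table <- function(staged) {
  specs <- list(
    radial_mm = "continuous", width_mm = "continuous",
    area_mm2 = "continuous", n_epe = "categorical",
    age = "continuous", psa = "continuous", pgg = "categorical",
    tumor_vol_group = "categorical", pni = "categorical",
    lvi = "categorical", am = "categorical", bm = "categorical",
    cm = "categorical", vm = "categorical", lnm = "categorical")
  specs <- specs[names(specs) %in% names(staged)]
  grp <- factor(ifelse(staged$bcr_event == 1, "BCR", "no BCR"),
                levels = c("no BCR", "BCR"))
  rows <- lapply(names(specs), function(v) {
    x <- staged[[v]]
    if (v == "n_epe") x <- pmin(x, 3)  # 1 / 2 / >=3 categories
    res <- tryCatch(compare_groups(x, grp, type = specs[[v]]),
                    error = function(e) list(test = NA, statistic = NA,
                                             p_value = NA))
    data.frame(variable = v, test = res$test,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.epe_parameter_table <- function(staged, adjust) {
  params <- c(radial_high = "radial_high", area_high = "area_high",
              multifocal = "multifocal")
  rows <- lapply(names(params), function(p) {
    un <- fit_cox(stats::as.formula(paste(
      "survival::Surv(time, bcr_event) ~", params[[p]])), staged)
    row <- data.frame(parameter = p,
                      hr = unname(un$hazard_ratio[1]),
                      ci_lower = unname(un$ci_lower[1]),
                      ci_upper = unname(un$ci_upper[1]),
                      p_value = unname(un$p_value[1]),
                      c_index = un$c_index, stringsAsFactors = FALSE)
    if (length(adjust)) {
      ad <- tryCatch(fit_cox(stats::as.formula(paste(
        "survival::Surv(time, bcr_event) ~", params[[p]], "+",
        paste(adjust, collapse = " + "))), staged),
        error = function(e) NULL)
      if (!is.null(ad)) {
        j <- match(params[[p]], names(ad$coefficients))
        row$hr_adj <- unname(ad$hazard_ratio[j])
        row$ci_lower_adj <- unname(ad$ci_lower[j])
        row$ci_upper_adj <- unname(ad$ci_upper[j])
        row$p_value_adj <- unname(ad$p_value[j])
      }
    }
    row
  })
  do.call(rbind, rows)
}

.uni_multi_table <- function(staged) {
  uni_terms <- c("age_high", "psa_high", "tumor_vol_group", "pni", "lvi",
                 "am", "bm", "cm", "vm", "substage", "lnm")
  uni_terms <- intersect(uni_terms, names(staged))
  uni <- lapply(uni_terms, function(v) {
    fit <- tryCatch(fit_cox(stats::as.formula(paste(
      "survival::Surv(time, bcr_event) ~", v)), staged),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cbind(variable = v, cox_table(fit), model = "univariable")
  })
  multi_terms <- intersect(c("psa_high", "tumor_vol_group", "lvi", "am",
                             "bm", "cm", "vm", "substage", "lnm"),
                           uni_terms)
  multi <- tryCatch({
    fit <- fit_cox(stats::as.formula(paste(
      "survival::Surv(time, bcr_event) ~",
      paste(multi_terms, collapse = " + "))), staged)
    cbind(variable = "multivariable", cox_table(fit), model = "multivariable")
  }, error = function(e) NULL)
  do.call(rbind, c(uni, list(multi)))
}

#' Export an analysis report to delimited files
#'
#' Writes each result table of a report (demographics, EPE-parameter Cox,
#' combined-bin Cox, uni/multivariable, Kaplan-Meier coordinates) as CSV
#' under `dir`, plus a JSON metadata file.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$demographics, "demographics.csv")
  wr(report$epe_cox, "epe_parameters_cox.csv")
  wr(report$combined_bin, "combined_bin_cox.csv")
  wr(report$uni_multi, "uni_multi_cox.csv")
  wr(report$km_substage$curves, "km_substage.csv")
  if (!is.null(report$km_cm)) wr(report$km_cm$curves, "km_cm_merged.csv")
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, file.path(dir, "metadata.json")))
}
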