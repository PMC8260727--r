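#' Generate a synthetic pT3a cohort
#'
#' Draws a patient-level cohort with the statistical structure assumed by
#' the substaging analysis: each patient carries one or more EPE foci whose
#' index (largest) radial distance falls in a sampled radial bin,
#' clinicopathologic covariates with realistic marginals, and a
#' biochemical-recurrence outcome drawn from a proportional-hazards model
#' whose hazard is `baseline_hazard * exp(group log HR + covariate effects)`
#' with administrative-plus-dropout censoring.
#'
#' Within-bin radial distances are uniform on the bin interval; the open
#' upper bin uses a shifted exponential. Focus widths (circumferential
#' lengths) are log-normal. Multifocal patients receive additional foci
#' with radial distances below the index focus; every focus carries a
#' distinct source-nodule identity so the focus count equals the number of
#' foci.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return An object of class `epe_cohort`: a list with
#'   * `patients`: one row per patient (EPE index measurements, focus
#'     count, covariates, follow-up `time` in months, `bcr_event` flag),
#'   * `foci`: one row per EPE focus (`patient_id`, `nodule_id`, `r_mm`,
#'     `w_mm`, `area_mm2`),
#'   * `config`: the generating configuration.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' head(coh$patients)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config"))
    stop("configuration error: config must be a cohort_config object")
  set.seed(seed)
  n <- config$n_patients
  lev <- .group_levels()
  p <- group_probabilities(config)
  grp <- sample(lev, n, replace = TRUE, prob = p)

  radial_bin <- as.integer(sub("^r(\\d).*", "\\1", grp))
  number_bin <- ifelse(grepl("_n2$", grp), 2L, 1L)
  # the merged top radial bin carries both focus-number levels
  r4 <- grp == "r4"
  number_bin[r4] <- 1L + stats::rbinom(sum(r4), 1, config$multifocal_prob)

  radial_mm <- .sample_radial(radial_bin)
  n_epe <- .sample_focus_count(number_bin)
  width_mm <- stats::rlnorm(n, meanlog = log(4), sdlog = 0.8)

  cov <- .sample_covariates(n)
  lp <- config$group_log_hr[grp]
  if (!is.null(config$covariate_effects))
    lp <- lp + .covariate_lp(cov, config$covariate_effects)

  out <- .sample_outcome(lp, config)

  patients <- data.frame(
    patient_id = seq_len(n),
    group = factor(grp, levels = lev),
    radial_bin = radial_bin,
    number_bin = number_bin,
    n_epe = n_epe,
    radial_mm = radial_mm,
    width_mm = width_mm,
    area_mm2 = radial_mm * width_mm,
    cov,
    has_epe = TRUE,
    has_svi = FALSE,
    time = out$time,
    bcr_event = out$event,
    stringsAsFactors = FALSE
  )

  foci <- .sample_foci(patients)
  structure(list(patients = patients, foci = foci, config = config),
            class = "epe_cohort")
}

#' @export
print.epe_cohort <- function(x, ...) {
  cat("Synthetic pT3a cohort: ", nrow(x$patients), " patients, ",
      nrow(x$foci), " EPE foci, ", sum(x$patients$bcr_event),
      " BCR events\n", sep = "")
  invisible(x)
}

.sample_radial <- function(radial_bin) {
  n <- length(radial_bin)
  r <- numeric(n)
  lo <- c(0.01, 0.75, 2, 5)[radial_bin]
  hi <- c(0.75, 2, 5, NA)[radial_bin]
  in4 <- radial_bin == 4L
  r[!in4] <- stats::runif(sum(!in4), lo[!in4], hi[!in4])
  r[in4] <- 5 + stats::rexp(sum(in4), rate = 0.5)
  r
}

.sample_focus_count <- function(number_bin) {
  n <- length(number_bin)
  cnt <- rep(1L, n)
  multi <- number_bin == 2L
  m <- sum(multi)
  if (m > 0) {
    # most multifocal cases have exactly two foci; a minority 3..9
    two <- stats::runif(m) < .epe_defaults$bifocal_n / .epe_defaults$multifocal_n
    extra <- sample(3:9, m, replace = TRUE, prob = 0.45^(0:6))
    cnt[multi] <- ifelse(two, 2L, extra)
  }
  cnt
}

.sample_covariates <- function(n) {
  data.frame(
    age = round(stats::rnorm(n, 66.0, 7.2), 1),
    psa = round(stats::rlnorm(n, meanlog = log(11.75), sdlog = 1.0), 2),
    pgg = sample(1:5, n, replace = TRUE,
                 prob = c(8, 126, 81, 71, 179) / 465),
    tumor_vol_group = sample(c("<=2", "2-5", ">5"), n, replace = TRUE,
                             prob = c(76, 223, 165) / 465),
    pni = stats::rbinom(n, 1, 442 / 465),
    lvi = stats::rbinom(n, 1, 96 / 465),
    am = stats::rbinom(n, 1, 105 / 465),
    bm = stats::rbinom(n, 1, 161 / 465),
    cm = stats::rbinom(n, 1, 227 / 465),
    vm = stats::rbinom(n, 1, 19 / 465),
    lnm = ifelse(stats::runif(n) < 236 / 465,
                 stats::rbinom(n, 1, 56 / 236), NA_integer_),
    stringsAsFactors = FALSE
  )
}

.covariate_lp <- function(cov, effects) {
  lp <- numeric(nrow(cov))
  for (nm in names(effects)) {
    x <- switch(nm,
                psa_log = log(cov$psa),
                tumor_vol = match(cov$tumor_vol_group, c("<=2", "2-5", ">5")) - 1,
                {
                  if (!nm %in% names(cov))
                    stop("configuration error: unknown covariate effect '", nm, "'")
                  v <- cov[[nm]]
                  ifelse(is.na(v), 0, v)
                })
    lp <- lp + effects[[nm]] * x
  }
  lp
}

.sample_outcome <- function(lp, config) {
  n <- length(lp)
  haz <- config$baseline_hazard * exp(lp)
  e <- stats::rexp(n)
  t_event <- (e / haz)^(1 / config$weibull_shape)
  c_drop <- if (config$dropout_rate > 0)
    stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  cens <- pmin(config$censor_horizon, c_drop)
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

.sample_foci <- function(patients) {
  n_epe <- patients$n_epe
  idx <- rep.int(seq_len(nrow(patients)), n_epe)
  first <- !duplicated(idx)
  r <- numeric(length(idx))
  r[first] <- patients$radial_mm            # index focus keeps the bin draw
  r[!first] <- stats::runif(sum(!first), 0.01, 1) *
    patients$radial_mm[idx[!first]]         # satellites never exceed the index
  w <- numeric(length(idx))
  w[first] <- patients$width_mm
  w[!first] <- stats::rlnorm(sum(!first), meanlog = log(3), sdlog = 0.8)
  data.frame(
    patient_id = patients$patient_id[idx],
    focus_id = stats::ave(idx, idx, FUN = seq_along),
    nodule_id = paste0("P", patients$patient_id[idx], "_N",
                       stats::ave(idx, idx, FUN = seq_along)),
    r_mm = r,
    w_mm = w,
    area_mm2 = r * w,
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort patient table
#'
#' The patient table round-trips through CSV with a stable column order, so
#' a rerun with the same configuration and seed reproduces the file
#' byte for byte.
#'
#' @param cohort an `epe_cohort` object (or a patient `data.frame`).
#' @param path output CSV path.
#' @return `write_cohort` invisibly returns the path; `read_cohort` returns
#'   the patient `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (inherits(cohort, "epe_cohort")) cohort$patients else cohort
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
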