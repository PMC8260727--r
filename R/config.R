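#' Default calibration constants for the synthetic pT3a cohort
#'
#' Marginal structure of the reference radical-prostatectomy cohort the
#' generator emulates: 465 pT3a patients; radial-distance bins of the EPE
#' index holding 99 / 283 / 83 patients for r <= 0.75 mm, 0.75 < r <= 2 mm
#' and r > 2 mm; 49/465 multifocal cases (42 of them with exactly two foci);
#' 255/465 biochemical-recurrence events. The r > 2 mm margin is split into
#' (2, 5] and > 5 mm bins with a configurable 80/20 default because the
#' finer split is not published.
#'
#' @format A named list of calibration constants.
#' @keywords internal
.epe_defaults <- list(
  n_patients     = 465L,
  n_radial       = c(99L, 283L, 83L),
  upper_split    = 0.8,          # fraction of the >2 mm margin in (2, 5]
  multifocal_n   = 49L,
  bifocal_n      = 42L,
  event_n        = 255L,
  # per-group hazard ratios of the combined (radial bin, focus-number) model,
  # reference group (1,1); "r4" is the merged (4,1)+(4,2) group
  group_hr = c(r1_n1 = 1, r2_n1 = 1.665, r3_n1 = 3.657,
               r1_n2 = 1.753, r2_n2 = 2.884, r3_n2 = 4.237, r4 = 4.203),
  combined_tier_hr = 2.526,      # per-level HR of the ordinal substage tier
  multifocal_hr    = 1.534,      # unadjusted HR of the >1 focus indicator
  cm_group_hr      = c(pT3a1_pos = 5.053, pT3a23_neg = 5.204)
)

#' Build a synthetic-cohort configuration
#'
#' Assembles and validates the full parameter set of the cohort generator:
#' radial-distance bin probabilities of the EPE index, multifocality
#' probability, per-group log hazard ratios of the combined
#' (radial bin, focus number) grouping, covariate marginals with their
#' (default zero) log-hazard effects, the exponential baseline hazard, and
#' the censoring model (administrative horizon plus independent exponential
#' dropout).
#'
#' Radial bins follow the staging convention: bin 1 is r <= 0.75 mm, bin 2
#' is 0.75 < r <= 2 mm, bin 3 is 2 < r <= 5 mm, bin 4 is r > 5 mm. Group
#' log-hazard ratios are indexed by the seven combined-group labels
#' `r1_n1, r2_n1, r3_n1, r1_n2, r2_n2, r3_n2, r4` (radial bin 4 is merged
#' across focus number); the reference `r1_n1` must be 0.
#'
#' When `baseline_hazard = NULL` (the default) the baseline rate is
#' calibrated by root finding so that the expected event fraction under the
#' configured group mixture and censoring model equals
#' `target_event_fraction`.
#'
#' @param n_patients cohort size (default 465).
#' @param radial_bin_probs probability vector over the four radial bins;
#'   must be non-negative and sum to 1.
#' @param multifocal_prob probability that a patient has more than one EPE
#'   focus.
#' @param group_log_hr named numeric vector of true log hazard ratios for
#'   the seven combined groups; `r1_n1` is the reference and must equal 0.
#' @param covariate_effects named numeric vector of log-hazard effects for
#'   generated covariates (default all zero; names as in the generated
#'   cohort table, e.g. `lvi`, `psa_log`).
#' @param baseline_hazard exponential baseline event rate per month, or
#'   `NULL` to calibrate it to `target_event_fraction`.
#' @param target_event_fraction expected fraction of patients with an
#'   observed event under the censoring model (default 255/465).
#' @param censor_horizon administrative censoring horizon in months.
#' @param dropout_rate rate (per month) of independent exponential dropout.
#' @param weibull_shape shape of the Weibull event-time law; 1 (default)
#'   gives exponential times and a proportional-hazards model that is exact
#'   at every time scale.
#' @param upper_split fraction of the r > 2 mm probability mass assigned to
#'   the (2, 5] bin when `radial_bin_probs` is left at its default.
#' @param joint_table optional 4 x 2 matrix of joint (radial bin, focus
#'   number bin) probabilities overriding the default independence coupling
#'   of the two marginals.
#' @param seed integer seed stored with the configuration.
#'
#' @return An object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cfg$baseline_hazard
#' @export
cohort_config <- function(n_patients = .epe_defaults$n_patients,
                          radial_bin_probs = NULL,
                          multifocal_prob =
                            .epe_defaults$multifocal_n / .epe_defaults$n_patients,
                          group_log_hr = log(.epe_defaults$group_hr),
                          covariate_effects = NULL,
                          baseline_hazard = NULL,
                          target_event_fraction =
                            .epe_defaults$event_n / .epe_defaults$n_patients,
                          censor_horizon = 84,
                          dropout_rate = 0.005,
                          weibull_shape = 1,
                          upper_split = .epe_defaults$upper_split,
                          joint_table = NULL,
                          seed = 1L) {
  if (is.null(radial_bin_probs)) {
    m <- .epe_defaults$n_radial / .epe_defaults$n_patients
    radial_bin_probs <- c(m[1], m[2], m[3] * upper_split, m[3] * (1 - upper_split))
  }
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1)
    stop("configuration error: n_patients must be a single integer >= 1")
  if (length(radial_bin_probs) != 4 || any(radial_bin_probs < 0) ||
      abs(sum(radial_bin_probs) - 1) > 1e-9)
    stop("configuration error: radial_bin_probs must be 4 non-negative ",
         "probabilities summing to 1")
  if (multifocal_prob < 0 || multifocal_prob > 1)
    stop("configuration error: multifocal_prob must lie in [0, 1]")
  lab <- .group_levels()
  if (!all(lab %in% names(group_log_hr)))
    stop("configuration error: group_log_hr must name all of ",
         paste(lab, collapse = ", "))
  group_log_hr <- group_log_hr[lab]
  if (abs(group_log_hr[["r1_n1"]]) > 1e-12)
    stop("configuration error: reference group r1_n1 must have log HR 0")
  if (!is.null(joint_table)) {
    if (!is.matrix(joint_table) || !all(dim(joint_table) == c(4, 2)) ||
        any(joint_table < 0) || abs(sum(joint_table) - 1) > 1e-9)
      stop("configuration error: joint_table must be a 4 x 2 probability matrix")
  }
  if (censor_horizon <= 0 || dropout_rate < 0 || weibull_shape <= 0)
    stop("configuration error: censoring/shape parameters out of range")

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    radial_bin_probs = as.numeric(radial_bin_probs),
    multifocal_prob = multifocal_prob,
    group_log_hr = group_log_hr,
    covariate_effects = covariate_effects,
    baseline_hazard = baseline_hazard,
    target_event_fraction = target_event_fraction,
    censor_horizon = censor_horizon,
    dropout_rate = dropout_rate,
    weibull_shape = weibull_shape,
    joint_table = joint_table,
    seed = as.integer(seed)
  ), class = "cohort_config")

  if (is.null(cfg$baseline_hazard)) {
    w <- group_probabilities(cfg)
    if (weibull_shape != 1) {
      cfg$baseline_hazard <- calibrate_baseline_hazard(
        cfg$group_log_hr, w, target_event_fraction,
        censor_horizon, dropout_rate, shape = weibull_shape)
    } else {
      cfg$baseline_hazard <- calibrate_baseline_hazard(
        cfg$group_log_hr, w, target_event_fraction,
        censor_horizon, dropout_rate)
    }
  }
  if (cfg$baseline_hazard <= 0)
    stop("configuration error: baseline_hazard must be > 0")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic pT3a cohort configuration\n")
  cat("  patients:         ", x$n_patients, "\n")
  cat("  radial bin probs: ", paste(signif(x$radial_bin_probs, 4), collapse = " "), "\n")
  cat("  multifocal prob:  ", signif(x$multifocal_prob, 4), "\n")
  cat("  baseline hazard:  ", signif(x$baseline_hazard, 4), "/month\n")
  cat("  censoring:        admin ", x$censor_horizon, " mo + dropout ",
      x$dropout_rate, "/mo\n", sep = "")
  cat("  target event frac:", signif(x$target_event_fraction, 4), "\n")
  invisible(x)
}

.group_levels <- function() {
  c("r1_n1", "r2_n1", "r3_n1", "r1_n2", "r2_n2", "r3_n2", "r4")
}

#' Joint probabilities of the seven combined groups
#'
#' Couples the radial-bin and focus-number marginals (independently unless
#' an explicit joint table is configured) and folds radial bin 4 across
#' focus number into the single merged group `r4`.
#'
#' @param config a [cohort_config()] object.
#' @return named probability vector over `r1_n1 ... r4`, summing to 1.
#' @export
group_probabilities <- function(config) {
  if (!is.null(config$joint_table)) {
    jt <- config$joint_table
  } else {
    jt <- outer(config$radial_bin_probs,
                c(1 - config$multifocal_prob, config$multifocal_prob))
  }
  p <- c(r1_n1 = jt[1, 1], r2_n1 = jt[2, 1], r3_n1 = jt[3, 1],
         r1_n2 = jt[1, 2], r2_n2 = jt[2, 2], r3_n2 = jt[3, 2],
         r4 = jt[4, 1] + jt[4, 2])
  p[.group_levels()]
}

#' Expected event fraction under the proportional-hazards censoring model
#'
#' For exponential event times with subject hazard `h0 * exp(lp)` and
#' censoring at the minimum of an administrative horizon `tau` and an
#' independent exponential dropout time with rate `mu`, the probability of
#' observing the event is `lambda / (lambda + mu) * (1 - exp(-(lambda + mu) tau))`
#' with `lambda = h0 * exp(lp)`. This averages that probability over a
#' mixture of linear predictors; for a Weibull event law (shape != 1) the
#' per-group probability is obtained by numerical integration.
#'
#' @param h0 baseline hazard (scale rate for shape 1).
#' @param log_hr vector of linear predictors (log hazard ratios).
#' @param weights mixture weights, same length as `log_hr`.
#' @param censor_horizon administrative horizon (months).
#' @param dropout_rate exponential dropout rate (per month).
#' @param shape Weibull shape (1 = exponential).
#' @return expected fraction of observed events.
#' @export
expected_event_fraction <- function(h0, log_hr, weights, censor_horizon,
                                    dropout_rate, shape = 1) {
  stopifnot(length(log_hr) == length(weights))
  lam <- h0 * exp(log_hr)
  if (shape == 1) {
    tot <- lam + dropout_rate
    p <- lam / tot * (1 - exp(-tot * censor_horizon))
  } else {
    # P(T <= min(tau, C)) with T Weibull(hazard lam * k t^(k-1)), C ~ Exp(mu)
    p <- vapply(lam, function(l) {
      f <- function(t) l * shape * t^(shape - 1) *
        exp(-l * t^shape - dropout_rate * t)
      stats::integrate(f, 0, censor_horizon, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  sum(weights * p) / sum(weights)
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Root-finds the baseline rate such that [expected_event_fraction()] under
#' the configured group mixture and censoring model equals the target.
#'
#' @inheritParams expected_event_fraction
#' @param target target event fraction in (0, 1).
#' @return the calibrated baseline hazard (per month).
#' @export
calibrate_baseline_hazard <- function(log_hr, weights, target,
                                      censor_horizon, dropout_rate,
                                      shape = 1) {
  if (target <= 0 || target >= 1)
    stop("configuration error: target event fraction must lie in (0, 1)")
  f <- function(h0) expected_event_fraction(h0, log_hr, weights,
                                            censor_horizon, dropout_rate,
                                            shape) - target
  stats::uniroot(f, lower = 1e-8, upper = 100, tol = 1e-12)$root
}
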