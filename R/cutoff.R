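#' Default candidate grids for cut-off scanning
#'
#' Literature-anchored candidate thresholds: radial-distance candidates
#' 0.5, 0.6, 0.75, 1.0, 1.1 and 2.0 mm (values proposed by earlier EPE
#' cut-off studies), and 2D-square-area candidates 0.5, 2.0 and 5.0 mm².
#'
#' @name cutoff_grids
#' @export
default_radial_grid <- function() c(0.5, 0.6, 0.75, 1.0, 1.1, 2.0)

#' @rdname cutoff_grids
#' @export
default_area_grid <- function() c(0.5, 2.0, 5.0)

#' Scan candidate cut-off values for a continuous EPE feature
#'
#' For each candidate threshold the feature is dichotomized (`feature >
#' candidate`) — or, in `"bin"` mode, binned by the whole candidate grid —
#' and a Cox model of the outcome on the thresholded feature (optionally
#' adjusted for covariates) is fitted. Candidates are compared by
#' Harrell's C; the selected cut-off is the candidate with the highest
#' C-index among those whose hazard ratio(s) for the feature term(s) are
#' all significant at `alpha`. If no candidate reaches significance the
#' highest-C candidate is returned with
#' `selection_rationale = "highest C-index only"`. Ties in C-index are
#' broken toward the smaller threshold, so the result does not depend on
#' candidate order.
#'
#' Candidates that produce an empty stratum (no patients on one side) are
#' skipped with a warning.
#'
#' @param feature positive numeric feature (e.g. radial distance in mm).
#' @param time,event outcome follow-up times and event flags.
#' @param candidates numeric candidate thresholds (>= 2).
#' @param mode `"dichotomize"` (default) or `"bin"`; in bin mode the model
#'   uses the full grid as bin edges and a candidate's significance is that
#'   of the dummy for the bin starting at the candidate.
#' @param data optional `data.frame` of adjustment covariates.
#' @param adjust character vector of covariate names in `data` to adjust
#'   for (default unadjusted).
#' @param alpha significance level of the HR filter.
#' @return An object of class `cutoff_scan`: list with `results` (one row
#'   per candidate: `cutoff`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `c_index`, `significant`), `selected_cutoff`, `selection_rationale`,
#'   `mode`.
#' @examples
#' set.seed(1)
#' d <- data.frame(r = runif(300, 0.1, 3))
#' d$time <- rexp(300, 0.02 * ifelse(d$r > 1, 3, 1))
#' d$event <- 1
#' scan_cutoffs(d$r, d$time, d$event, candidates = c(0.5, 1, 2))
#' @export
scan_cutoffs <- function(feature, time, event, candidates,
                         mode = c("dichotomize", "bin"),
                         data = NULL, adjust = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(candidates) < 1) stop("input error: need at least one candidate")
  if (any(feature <= 0)) stop("input error: feature must be strictly positive")
  candidates <- sort(unique(candidates))
  usable <- vapply(candidates, function(cc)
    any(feature <= cc) && any(feature > cc), logical(1))
  if (any(!usable))
    warning("skipping candidate(s) with an empty stratum: ",
            paste(candidates[!usable], collapse = ", "))
  cand <- candidates[usable]
  if (length(cand) == 0) stop("input error: no usable candidate")

  df <- data.frame(time = time, event = event)
  rhs_adj <- ""
  if (!is.null(adjust)) {
    df <- cbind(df, data[, adjust, drop = FALSE])
    rhs_adj <- paste("+", paste(adjust, collapse = " + "))
  }

  if (mode == "bin") {
    df$fbin <- cut(feature, breaks = c(-Inf, cand, Inf), right = TRUE)
    full <- fit_cox(stats::as.formula(paste(
      "survival::Surv(time, event) ~ fbin", rhs_adj)), df)
    terms_bin <- grep("^fbin", names(full$coefficients))
  }

  rows <- lapply(seq_along(cand), function(i) {
    cc <- cand[i]
    if (mode == "dichotomize") {
      df$fpos <- as.integer(feature > cc)
      fit <- fit_cox(stats::as.formula(paste(
        "survival::Surv(time, event) ~ fpos", rhs_adj)), df)
      j <- match("fpos", names(fit$coefficients))
    } else {
      fit <- full
      j <- terms_bin[i]   # dummy of the bin whose lower edge is cc
    }
    data.frame(cutoff = cc, hr = fit$hazard_ratio[j],
               ci_lower = fit$ci_lower[j], ci_upper = fit$ci_upper[j],
               p_value = fit$p_value[j], c_index = fit$c_index,
               significant = fit$p_value[j] < alpha, row.names = NULL)
  })
  res <- do.call(rbind, rows)

  pick <- function(rows_df) {
    ord <- order(-rows_df$c_index, rows_df$cutoff)
    rows_df$cutoff[ord[1]]
  }
  if (any(res$significant)) {
    sel <- pick(res[res$significant, , drop = FALSE])
    rationale <- "highest C-index with significant HR"
  } else {
    sel <- pick(res)
    rationale <- "highest C-index only"
  }
  structure(list(results = res, selected_cutoff = sel,
                 selection_rationale = rationale, mode = mode,
                 alpha = alpha, candidates = candidates),
            class = "cutoff_scan")
}

#' Simulate a cohort with a step hazard at a known change point
#'
#' Validation harness for [scan_cutoffs()]: a continuous feature is drawn
#' uniformly over `feature_range` and event times follow an exponential
#' proportional-hazards model whose hazard jumps by `hr` when the feature
#' exceeds `threshold`, with the package's standard administrative +
#' dropout censoring.
#'
#' @param n subjects.
#' @param threshold true change point (same units as the feature).
#' @param hr hazard ratio above vs below the change point.
#' @param feature_range range of the uniform feature.
#' @param target_event_fraction,censor_horizon,dropout_rate censoring
#'   model, as in [simulate_group_survival()].
#' @param seed integer seed.
#' @return `data.frame` with `feature`, `time`, `event`.
#' @export
simulate_changepoint_cohort <- function(n, threshold = 0.75, hr = 2.5,
                                        feature_range = c(0.05, 3),
                                        target_event_fraction = 255 / 465,
                                        censor_horizon = 84,
                                        dropout_rate = 0.005, seed = 1L) {
  set.seed(seed)
  feature <- stats::runif(n, feature_range[1], feature_range[2])
  p_above <- (feature_range[2] - threshold) / diff(feature_range)
  h0 <- calibrate_baseline_hazard(c(0, log(hr)), c(1 - p_above, p_above),
                                  target_event_fraction, censor_horizon,
                                  dropout_rate)
  haz <- h0 * exp(log(hr) * (feature > threshold))
  t_event <- stats::rexp(n) / haz
  cens <- pmin(censor_horizon,
               if (dropout_rate > 0) stats::rexp(n, dropout_rate) else Inf)
  data.frame(feature = feature, time = pmin(t_event, cens),
             event = as.integer(t_event <= cens))
}

#' @export
print.cutoff_scan <- function(x, digits = 3, ...) {
  cat("Cut-off scan (", x$mode, " mode)\n", sep = "")
  print(cbind(round(x$results[1:6], digits),
              significant = x$results$significant))
  cat("selected cut-off:", x$selected_cutoff,
      "(", x$selection_rationale, ")\n")
  invisible(x)
}
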