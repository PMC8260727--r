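#' Fit a Cox proportional-hazards model
#'
#' Thin, validated wrapper around [survival::coxph()] returning the
#' quantities reported in substaging analyses: per-covariate hazard ratio
#' with Wald 95% confidence interval and p-value, and Harrell's C computed
#' on the fitted linear predictor. Efron's tie correction is the default.
#'
#' @param formula a model formula whose left side is
#'   `survival::Surv(time, event)`.
#' @param data `data.frame` holding the variables; rows with missing
#'   model variables are dropped (complete-case analysis, as when a
#'   partially evaluated covariate such as lymph-node status enters the
#'   model).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level for the Wald interval.
#' @return An object of class `cox_fit`: list with `coefficients` (log
#'   hazard ratios), `hazard_ratio`, `ci_lower`, `ci_upper`, `se`,
#'   `p_value`, `c_index`, `n`, `n_events`, and the underlying `fit`.
#' @examples
#' d <- data.frame(time = c(5, 8, 2, 9, 3, 7), event = 1,
#'                 x = c(1, 0, 1, 0, 1, 0))
#' fit_cox(survival::Surv(time, event) ~ x, d)
#' @export
fit_cox <- function(formula, data, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  fit <- tryCatch(
    survival::coxph(formula, data = data, ties = ties),
    error = function(e) stop("fit error: ", conditionMessage(e)),
    warning = function(w) {
      # refit, surfacing convergence problems as diagnostics
      f <- suppressWarnings(survival::coxph(formula, data = data, ties = ties))
      attr(f, "diagnostic") <- conditionMessage(w)
      f
    })
  if (fit$nevent == 0) stop("input error: no events in the data")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  conc <- fit$concordance[["concordance"]]
  structure(list(
    coefficients = beta,
    hazard_ratio = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    se = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    c_index = conc,
    n = fit$n,
    n_events = fit$nevent,
    ties = ties,
    diagnostic = attr(fit, "diagnostic"),
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  tab <- data.frame(HR = x$hazard_ratio, lower = x$ci_lower,
                    upper = x$ci_upper, p = signif(x$p_value, digits))
  cat("Cox proportional hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(round(tab[1:3], digits = digits))
  cat("p-values:", signif(x$p_value, digits), "\n")
  cat("Harrell's C =", round(x$c_index, digits), "\n")
  invisible(x)
}

#' Summarise a Cox fit as a result table
#'
#' @param fit a `cox_fit`.
#' @return `data.frame` with one row per covariate: `term`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `c_index`.
#' @export
cox_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             hr = unname(fit$hazard_ratio),
             ci_lower = unname(fit$ci_lower),
             ci_upper = unname(fit$ci_upper),
             p_value = unname(fit$p_value),
             c_index = fit$c_index,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the higher risk score
#' belongs to the subject with the earlier event. A pair is comparable
#' when the shorter observed time ends in an event; tied risk scores count
#' one half. Computed via [survival::concordance()].
#'
#' @param risk_scores numeric risk scores (higher = higher hazard).
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return the concordance index in `[0, 1]`.
#' @examples
#' harrell_c(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))
#' @export
harrell_c <- function(risk_scores, time, event) {
  stopifnot(length(risk_scores) == length(time),
            length(time) == length(event))
  cf <- survival::concordance(survival::Surv(time, event) ~ risk_scores,
                              reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("undefined result: no comparable pairs under censoring")
  cf$concordance
}

#' Kaplan-Meier estimate with log-rank comparison
#'
#' Product-limit survival estimate, overall or per group, with the
#' log-rank chi-square test across groups.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group optional group labels.
#' @return An object of class `km_curves`: list with `curves` (a
#'   `data.frame`: `group`, `time`, `n_risk`, `n_event`, `survival`) and,
#'   for >= 2 groups, `logrank_chisq`, `logrank_df`, `logrank_p`.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))$curves
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- droplevels(as.factor(group))
  if (length(time) == 0 || nlevels(group) == 0 || anyNA(group))
    stop("input error: every group needs at least one subject")
  d <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  ss <- summary(sf, censored = FALSE)
  grp <- if (is.null(ss$strata)) rep(levels(d$group)[1], length(ss$time))
         else sub("^group=", "", as.character(ss$strata))
  curves <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, survival = ss$surv,
                       stringsAsFactors = FALSE)
  res <- list(curves = curves, survfit = sf)
  if (nlevels(d$group) > 1) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    df <- length(lr$n) - 1
    res$logrank_chisq <- lr$chisq
    res$logrank_df <- df
    res$logrank_p <- stats::pchisq(lr$chisq, df, lower.tail = FALSE)
  }
  structure(res, class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Kaplan-Meier estimate:", length(unique(x$curves$group)), "group(s),",
      nrow(x$curves), "event times\n")
  if (!is.null(x$logrank_chisq))
    cat("log-rank chi-square =", round(x$logrank_chisq, 3), "on",
        x$logrank_df, "df, p =", signif(x$logrank_p, 3), "\n")
  invisible(x)
}

#' Two-group comparison for demographics tables
#'
#' Student's t-test (equal variances) for continuous variables and the
#' chi-square test (without continuity correction) for categorical ones,
#' as used to compare recurrence vs non-recurrence groups in cohort
#' demographics tables.
#'
#' @param x a numeric vector (continuous variable) or a vector treated as
#'   categorical.
#' @param group two-level group labels aligned with `x`.
#' @param type `"auto"` (numeric with > 5 distinct values is continuous),
#'   `"continuous"` or `"categorical"`.
#' @return list with `test` (`"t"` or `"chisq"`), `statistic`, `p_value`,
#'   and `df`.
#' @examples
#' compare_groups(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
compare_groups <- function(x, group, type = c("auto", "continuous",
                                              "categorical")) {
  type <- match.arg(type)
  keep <- !is.na(x) & !is.na(group)
  x <- x[keep]; group <- droplevels(as.factor(group[keep]))
  if (type == "auto")
    type <- if (is.numeric(x) && length(unique(x)) > 5) "continuous"
            else "categorical"
  if (type == "continuous") {
    if (nlevels(group) != 2)
      stop("input error: t-test requires exactly two groups")
    if (stats::var(x) == 0)
      return(list(test = "t", statistic = 0, p_value = 1,
                  df = length(x) - 2))
    tt <- stats::t.test(x ~ group, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter))
  } else {
    tab <- table(x, group)
    if (any(dim(tab) < 2))
      stop("input error: degenerate contingency table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value, df = unname(ct$parameter))
  }
}
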