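#' Assign the pathological T stage label
#'
#' Seminal vesicle invasion defines pT3b regardless of EPE; extraprostatic
#' extension without seminal vesicle invasion defines pT3a; organ-confined
#' disease is pT2.
#'
#' @param has_epe logical: extraprostatic extension present.
#' @param has_svi logical: seminal vesicle invasion present.
#' @return character vector of `"pT2"`, `"pT3a"`, `"pT3b"`.
#' @examples
#' assign_pt_stage(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
#' @export
assign_pt_stage <- function(has_epe, has_svi) {
  ifelse(has_svi, "pT3b", ifelse(has_epe, "pT3a", "pT2"))
}

#' Assign the combined (radial bin, focus number) group
#'
#' Bins the EPE-index radial distance into four left-open, right-closed
#' intervals — r <= 0.75, 0.75 < r <= 2, 2 < r <= 5, r > 5 mm — and the
#' focus count into n <= 1 vs n > 1. The top radial bin is merged across
#' focus number into a single group.
#'
#' @param r EPE-index radial distance in mm (> 0 for a pT3a case).
#' @param n EPE focus count (>= 1).
#' @return `data.frame` with `radial_bin` (1-4), `number_bin` (1, 2; `NA`
#'   for the merged bin 4) and `group` (factor with levels
#'   `r1_n1 ... r3_n2, r4`, reference `r1_n1`).
#' @examples
#' assign_combined_bin(c(0.75, 3.0, 6.1), c(1, 2, 1))
#' @export
assign_combined_bin <- function(r, n) {
  if (any(r <= 0) || any(n < 1) || any(n != round(n)))
    stop("domain error: require r > 0 and integer n >= 1")
  # right-closed bins: boundary values (0.75, 2, 5) fall in the lower bin
  radial_bin <- 1L + (r > 0.75) + (r > 2) + (r > 5)
  number_bin <- ifelse(n > 1, 2L, 1L)
  group <- ifelse(radial_bin == 4L, "r4",
                  paste0("r", radial_bin, "_n", number_bin))
  data.frame(radial_bin = radial_bin,
             number_bin = ifelse(radial_bin == 4L, NA_integer_, number_bin),
             group = factor(group, levels = .group_levels()))
}

#' Assign the three-tier pT3a substage
#'
#' The substage is a deterministic function of the EPE-index radial
#' distance `r` and the focus count `n`:
#'
#' * **pT3a1** — r <= 0.75 mm, any number of foci;
#' * **pT3a2** — 0.75 < r <= 2 mm and a single focus;
#' * **pT3a3** — r > 2 mm (any number of foci), or 0.75 < r <= 2 mm with
#'   two or more foci.
#'
#' @inheritParams assign_combined_bin
#' @return factor with levels `pT3a1`, `pT3a2`, `pT3a3`.
#' @examples
#' assign_substage(c(0.5, 1.5, 1.5, 2.0, 2.01), c(3, 1, 2, 1, 1))
#' @export
assign_substage <- function(r, n) {
  if (any(r <= 0) || any(n < 1) || any(n != round(n)))
    stop("domain error: require r > 0 and integer n >= 1")
  sub <- ifelse(r <= 0.75, "pT3a1",
                ifelse(r <= 2 & n == 1, "pT3a2", "pT3a3"))
  factor(sub, levels = c("pT3a1", "pT3a2", "pT3a3"))
}

#' Combine substage with circumferential-margin status
#'
#' Crosses the collapsed substage ({pT2, pT3a1, pT3a2/3}) with the
#' circumferential-margin (CM) sign, and merges the two prognostically
#' indistinguishable middle groups — pT3a1 with positive CM and pT3a2/3
#' with negative CM — into one ordinal level:
#'
#' * level 1 = pT3a1−, level 2 = pT3a1+ or pT3a2/3−, level 3 = pT3a2/3+;
#' * pT2 cases keep their own reference labels (`pT2-`, `pT2+`).
#'
#' @param pt_stage `"pT2"` or `"pT3a"` (vector).
#' @param substage substage factor/character; required (non-`NA`) exactly
#'   when `pt_stage == "pT3a"`.
#' @param cm_positive logical circumferential-margin involvement; must not
#'   be missing.
#' @return `data.frame` with `cm_group` (six labels) and `cm_merged_group`
#'   (factor: `pT2-`, `pT2+`, `level1`, `level2`, `level3`).
#' @examples
#' assign_cm_group("pT3a", "pT3a1", TRUE)
#' @export
assign_cm_group <- function(pt_stage, substage, cm_positive) {
  if (any(is.na(cm_positive)))
    stop("input error: circumferential-margin flag is missing")
  substage <- as.character(substage)
  if (any(pt_stage == "pT3a" & (is.na(substage) | !nzchar(substage))))
    stop("input error: substage required for pT3a cases")
  base <- ifelse(pt_stage == "pT2", "pT2",
                 ifelse(substage == "pT3a1", "pT3a1", "pT3a2/3"))
  sign <- ifelse(cm_positive, "+", "-")
  cm_group <- paste0(base, sign)
  merged <- ifelse(base == "pT2", cm_group,
                   ifelse(cm_group == "pT3a1-", "level1",
                          ifelse(cm_group == "pT3a2/3+", "level3", "level2")))
  data.frame(
    cm_group = factor(cm_group, levels = c("pT2-", "pT2+", "pT3a1-",
                                           "pT3a1+", "pT3a2/3-", "pT3a2/3+")),
    cm_merged_group = factor(merged, levels = c("pT2-", "pT2+", "level1",
                                                "level2", "level3"))
  )
}

#' Recover the substage from a combined group label
#'
#' Cross-check between the two classifiers: combined bins map onto
#' substages as (1, .) -> pT3a1; (2, 1) -> pT3a2; (2, 2), (3, .), (4, .)
#' -> pT3a3.
#'
#' @param group combined-group factor/character (`r1_n1 ... r4`).
#' @return substage factor.
#' @export
substage_from_group <- function(group) {
  g <- as.character(group)
  sub <- ifelse(g %in% c("r1_n1", "r1_n2"), "pT3a1",
                ifelse(g == "r2_n1", "pT3a2", "pT3a3"))
  factor(sub, levels = c("pT3a1", "pT3a2", "pT3a3"))
}

#' Stage a cohort table
#'
#' Applies the full staging layer to a patient table: pT stage from the
#' EPE/SVI flags, combined (radial bin, focus number) group, three-tier
#' substage and CM-combined grouping. pT2 records pass through with an
#' undefined substage.
#'
#' @param patients `data.frame` with columns `radial_mm`, `n_epe`, and
#'   optionally `has_epe`, `has_svi` (default `TRUE`/`FALSE`) and `cm`
#'   (0/1 circumferential-margin involvement).
#' @return the input with columns `pt_stage`, `radial_bin`, `number_bin`,
#'   `group`, `substage`, and (when `cm` is present) `cm_group`,
#'   `cm_merged_group` appended (existing columns of those names are
#'   recomputed).
#' @examples
#' stage_cohort(data.frame(radial_mm = c(0.4, 1.1), n_epe = c(1, 3),
#'                         cm = c(0, 1)))
#' @export
stage_cohort <- function(patients) {
  req <- c("radial_mm", "n_epe")
  miss <- setdiff(req, names(patients))
  if (length(miss))
    stop("validation error: missing columns: ", paste(miss, collapse = ", "))
  has_epe <- if ("has_epe" %in% names(patients)) patients$has_epe else TRUE
  has_svi <- if ("has_svi" %in% names(patients)) patients$has_svi else FALSE
  patients$pt_stage <- assign_pt_stage(has_epe, has_svi)

  idx <- patients$pt_stage == "pT3a"
  patients$radial_bin <- NA_integer_
  patients$number_bin <- NA_integer_
  patients$group <- factor(NA, levels = .group_levels())
  patients$substage <- factor(NA, levels = c("pT3a1", "pT3a2", "pT3a3"))
  if (any(idx)) {
    cb <- assign_combined_bin(patients$radial_mm[idx], patients$n_epe[idx])
    patients$radial_bin[idx] <- cb$radial_bin
    patients$number_bin[idx] <- cb$number_bin
    patients$group[idx] <- cb$group
    patients$substage[idx] <- assign_substage(patients$radial_mm[idx],
                                              patients$n_epe[idx])
  }
  if ("cm" %in% names(patients) && all(patients$pt_stage %in% c("pT2", "pT3a"))) {
    cg <- assign_cm_group(patients$pt_stage, as.character(patients$substage),
                          patients$cm > 0)
    patients$cm_group <- cg$cm_group
    patients$cm_merged_group <- cg$cm_merged_group
  }
  patients
}
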