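#' Capsule baseline polyline
#'
#' The reference line against which EPE protrusion is measured: an ordered
#' planar polyline in millimetres tracing the outer margin of the prostatic
#' capsule. Zones that lack a true capsule layer (anterior and urethral
#' zones) are marked as gap spans and later replaced by a straight
#' imaginary line with [impute_baseline()].
#'
#' @param points numeric n x 2 matrix (or data.frame) of (x, y) coordinates
#'   in mm, ordered along the capsule.
#' @param gap_spans optional list of integer pairs `c(i, j)` (i < j):
#'   between points `i` and `j` the capsule is absent; any recorded points
#'   strictly between them belong to the gap.
#' @return An object of class `capsule_baseline`.
#' @export
capsule_baseline <- function(points, gap_spans = NULL) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2 || nrow(pts) < 2)
    stop("baseline error: points must be an n x 2 numeric matrix with n >= 2")
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d == 0))
    stop("baseline error: consecutive baseline points must be distinct")
  if (!is.null(gap_spans)) {
    for (sp in gap_spans) {
      if (length(sp) != 2 || sp[1] >= sp[2] ||
          sp[1] < 1 || sp[2] > nrow(pts))
        stop("baseline error: gap span must be a valid index pair (i, j), i < j")
    }
  }
  structure(list(points = unname(pts), gap_spans = gap_spans),
            class = "capsule_baseline")
}

#' Impute missing capsule as a straight imaginary line
#'
#' Replaces every gap span by the straight chord joining the capsule
#' endpoints that flank it: points recorded inside a gap are dropped and
#' the polyline runs directly between the flanking endpoints. The result
#' carries no gaps and is suitable for [measure_focus()].
#'
#' @param baseline a [capsule_baseline()].
#' @return a gap-free `capsule_baseline`.
#' @export
impute_baseline <- function(baseline) {
  stopifnot(inherits(baseline, "capsule_baseline"))
  if (is.null(baseline$gap_spans) || length(baseline$gap_spans) == 0)
    return(baseline)
  n <- nrow(baseline$points)
  drop <- logical(n)
  for (sp in baseline$gap_spans) {
    if (sp[1] <= 1 && sp[2] >= n)
      stop("baseline error: gap covers the whole capsule; no flanking capsule to join")
    if (sp[2] - sp[1] > 1) drop[(sp[1] + 1):(sp[2] - 1)] <- TRUE
  }
  capsule_baseline(baseline$points[!drop, , drop = FALSE])
}

# project one point onto a polyline (vectorized over segments): min distance,
# arc-length coordinate of the foot, and side sign at the nearest segment
# (+1 = left of the traversal direction)
.project_point <- function(p, pts, cumlen) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) / len2
  t <- pmax(0, pmin(1, t))
  fx <- a[, 1] + t * ab[, 1]
  fy <- a[, 2] + t * ab[, 2]
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  i <- which.min(d2)
  cross <- ab[i, 1] * (p[2] - a[i, 2]) - ab[i, 2] * (p[1] - a[i, 1])
  list(d2 = d2[i], s = cumlen[i] + t[i] * (cumlen[i + 1] - cumlen[i]),
       side = sign(cross))
}

.cum_length <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# resample a closed polygon boundary at most `step` apart (vertices kept)
.densify_ring <- function(poly, step) {
  n <- nrow(poly)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.validate_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop("input error: polygon needs at least 3 vertices")
  seg <- function(i) list(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      si <- seg(i); sj <- seg(j)
      if (.segments_intersect(si[[1]], si[[2]], sj[[1]], sj[[2]]))
        stop("input error: polygon is self-intersecting")
    }
  }
  invisible(TRUE)
}

#' Measure one EPE focus against the capsule baseline
#'
#' Computes the three quantitative EPE parameters of a tumor protrusion:
#'
#' * **radial distance** `r` — the maximum perpendicular distance from the
#'   protrusion boundary (outward side only) to the baseline polyline;
#' * **circumferential length** `w` — the extent of the protrusion's
#'   footprint along the baseline, i.e. the baseline arc length between the
#'   two extreme projection points of the polygon;
#' * **2D square area** — the product r x w, the rectangular proxy for
#'   the extent of extraprostatic spread, regardless of contour shape.
#'
#' The polygon boundary is densified at `densify` mm before taking the
#' maximum so that edge interiors cannot exceed vertices unnoticed. The
#' outward side of the baseline defaults to `"auto"` (the side holding the
#' deepest excursion of the polygon); pass `"left"` or `"right"` relative
#' to the baseline's traversal direction to fix it. A polygon that lies
#' entirely on the inward side yields a no-EPE signal (`no_epe = TRUE`,
#' zero measurements) rather than an error.
#'
#' @param polygon n x 2 numeric matrix of polygon vertices (mm); the ring
#'   is closed implicitly (a repeated last vertex is tolerated).
#' @param baseline a [capsule_baseline()]; gaps are imputed automatically.
#' @param outward `"auto"`, `"left"` or `"right"`.
#' @param densify boundary sampling step in mm.
#' @return list with `radial_mm`, `width_mm`, `area_mm2`, `no_epe`.
#' @examples
#' base <- capsule_baseline(rbind(c(-5, 0), c(10, 0)))
#' rect <- rbind(c(0, 0), c(3, 0), c(3, 1.2), c(0, 1.2))
#' measure_focus(rect, base)
#' @export
measure_focus <- function(polygon, baseline,
                          outward = c("auto", "left", "right"),
                          densify = 0.01) {
  outward <- match.arg(outward)
  poly <- as.matrix(polygon)
  if (!is.numeric(poly) || ncol(poly) != 2)
    stop("input error: polygon must be an n x 2 numeric matrix")
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  .validate_simple_polygon(poly)
  base <- impute_baseline(baseline)
  pts <- base$points
  cumlen <- .cum_length(pts)

  samp <- .densify_ring(poly, densify)
  proj <- lapply(seq_len(nrow(samp)), function(i)
    .project_point(samp[i, ], pts, cumlen))
  d <- sqrt(vapply(proj, `[[`, numeric(1), "d2"))
  s <- vapply(proj, `[[`, numeric(1), "s")
  side <- vapply(proj, `[[`, numeric(1), "side")

  out_sign <- switch(outward,
                     left = 1,
                     right = -1,
                     auto = {
                       mx <- c(`-1` = suppressWarnings(max(d[side < 0], 0)),
                               `1` = suppressWarnings(max(d[side > 0], 0)))
                       if (mx[["1"]] >= mx[["-1"]]) 1 else -1
                     })
  outward_pts <- side == out_sign & d > 1e-12
  if (!any(outward_pts))
    return(list(radial_mm = 0, width_mm = 0, area_mm2 = 0, no_epe = TRUE))
  r <- max(d[outward_pts])
  w <- max(s) - min(s)
  list(radial_mm = r, width_mm = w, area_mm2 = r * w, no_epe = FALSE)
}

#' Classify EPE contour shape
#'
#' Two contour types of extraprostatic protrusion are distinguished: the
#' church-spire type, whose radial distance exceeds two times its
#' circumferential length, and the broad-based sessile type (all other
#' cases, including the boundary r = 2w).
#'
#' @param radial_mm radial distance(s), mm, >= 0.
#' @param width_mm circumferential length(s), mm, > 0.
#' @return character vector, `"church_spire"` or `"broad_sessile"`.
#' @examples
#' classify_shape(c(2.1, 2.0, 0.4), c(1, 1, 6.5))
#' @export
classify_shape <- function(radial_mm, width_mm) {
  if (any(radial_mm < 0) || any(width_mm < 0))
    stop("domain error: negative EPE measurements")
  if (any(width_mm == 0))
    stop("domain error: circumferential length must be positive")
  ifelse(radial_mm > 2 * width_mm, "church_spire", "broad_sessile")
}

#' Count EPE foci by source-nodule identity
#'
#' Protrusions connected to the same tumor nodule count as one EPE; those
#' arising from separate tumors count separately. The focus count is
#' therefore the number of distinct nodule identities.
#'
#' @param foci a `data.frame` with a `nodule_id` column, or a vector of
#'   nodule identifiers.
#' @return integer focus count.
#' @examples
#' count_epe_foci(c("A", "A", "B"))
#' @export
count_epe_foci <- function(foci) {
  ids <- if (is.data.frame(foci)) foci$nodule_id else foci
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(as.character(ids))))
    stop("input error: every focus must carry a nodule_id")
  length(unique(ids))
}

#' Select the EPE index focus
#'
#' In multifocal cases one focus — the EPE index — represents the case for
#' staging: the focus with the longest radial distance. Ties are broken by
#' the larger 2D square area, then by first occurrence.
#'
#' @param foci `data.frame` with columns `r_mm` and (optionally) `area_mm2`.
#' @return the selected row of `foci`.
#' @export
select_epe_index <- function(foci) {
  if (!is.data.frame(foci) || nrow(foci) == 0)
    stop("input error: foci must be a non-empty data.frame")
  if (is.null(foci$r_mm)) stop("input error: foci must have a r_mm column")
  area <- if (is.null(foci$area_mm2)) rep(0, nrow(foci)) else foci$area_mm2
  ord <- order(-foci$r_mm, -area)
  foci[ord[1], , drop = FALSE]
}

#' Measure all foci of a geometry fixture
#'
#' Applies [measure_focus()] to every focus polygon of a fixture (see
#' [generate_geometry_fixture()]) and returns the per-focus measurement
#' table with shape classes.
#'
#' @param fixture a `geometry_fixture` object or a directory written by
#'   [write_geometry_fixture()].
#' @param densify boundary sampling step passed to [measure_focus()].
#' @return `data.frame` with columns `focus_id`, `nodule_id`, `r_mm`,
#'   `w_mm`, `area_mm2`, `shape_class`.
#' @export
measure_fixture <- function(fixture, densify = 0.01) {
  if (is.character(fixture)) fixture <- read_geometry_fixture(fixture)
  base <- impute_baseline(fixture$baseline)
  rows <- lapply(seq_along(fixture$foci), function(i) {
    f <- fixture$foci[[i]]
    m <- measure_focus(f$polygon, base, outward = "left", densify = densify)
    data.frame(focus_id = i, nodule_id = f$nodule_id,
               r_mm = m$radial_mm, w_mm = m$width_mm, area_mm2 = m$area_mm2,
               shape_class = classify_shape(m$radial_mm, m$width_mm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
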