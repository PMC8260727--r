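#' Minimal WKT helpers for planar contours
#'
#' Serialize / parse `LINESTRING` and `POLYGON` well-known-text geometries.
#' Only the single-ring planar forms used for capsule baselines and EPE
#' focus contours are supported.
#'
#' @param points n x 2 numeric matrix.
#' @return `wkt_linestring`/`wkt_polygon` return a WKT string;
#'   `parse_wkt` returns a list with `type` (`"LINESTRING"` or `"POLYGON"`)
#'   and `points` (n x 2 matrix; polygon rings are returned unclosed).
#' @keywords internal
#' @export
wkt_linestring <- function(points) {
  paste0("LINESTRING (",
         paste(apply(points, 1, function(p) paste(format(p[1], digits = 17),
                                                  format(p[2], digits = 17))),
               collapse = ", "), ")")
}

#' @rdname wkt_linestring
#' @export
wkt_polygon <- function(points) {
  pts <- rbind(points, points[1, ])  # close the ring
  paste0("POLYGON ((",
         paste(apply(pts, 1, function(p) paste(format(p[1], digits = 17),
                                               format(p[2], digits = 17))),
               collapse = ", "), "))")
}

#' @rdname wkt_linestring
#' @param text a WKT string.
#' @export
parse_wkt <- function(text) {
  text <- trimws(text)
  type <- toupper(sub("^([A-Za-z]+).*", "\\1", text))
  body <- gsub("^[A-Za-z]+\\s*\\(+|\\)+$", "", text)
  coords <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  pts <- t(vapply(coords, function(s) as.numeric(s[nzchar(s)]), numeric(2)))
  if (type == "POLYGON" && nrow(pts) > 1 &&
      all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (!type %in% c("LINESTRING", "POLYGON"))
    stop("input error: unsupported WKT type '", type, "'")
  list(type = type, points = pts)
}

# one random protrusion on a straight baseline along the x axis
# (outward = +y): footprint [x0, x0+width], apex height exactly `height`
.straight_protrusion <- function(x0, height, width) {
  k <- sample(1:4, 1)
  xt <- x0 + sort(stats::runif(k, 0.05, 0.95)) * width
  yt <- stats::runif(k, 0.3, 0.95) * height
  yt[sample(k, 1)] <- height
  rbind(c(x0, 0), cbind(xt, yt), c(x0 + width, 0))
}

#' Generate a geometry fixture with known ground truth
#'
#' Constructs a capsule baseline and EPE focus polygons whose true radial
#' distance and footprint width are known by construction, for validating
#' the measurement layer. Straight baselines carry randomized convex-ish
#' protrusions (apex height = true radial distance, base width = true
#' circumferential length). Curved baselines (circular-arc capsule) carry
#' chord-mounted triangular protrusions whose apex sits at the known
#' perpendicular height above one baseline chord. A gap variant records a
#' capsule gap to exercise straight-chord imputation.
#'
#' @param n_foci number of protrusions.
#' @param heights range (min, max) of true radial distances in mm.
#' @param widths range (min, max) of true footprint widths in mm.
#' @param baseline_type `"straight"`, `"arc"` or `"gap"`.
#' @param duplicate_nodule_prob probability that a protrusion shares the
#'   nodule identity of the previous one (drives the focus-counting rule).
#' @param seed integer seed.
#' @return An object of class `geometry_fixture`: list with `baseline`
#'   (a [capsule_baseline()]; traversal direction is such that outward is
#'   the left side), `foci` (list of `polygon`, `nodule_id`, `true_r`,
#'   `true_w`, `true_shape`), and `expected_focus_count`.
#' @examples
#' fx <- generate_geometry_fixture(5, seed = 1)
#' fx$foci[[1]]$true_r
#' @export
generate_geometry_fixture <- function(n_foci = 10,
                                      heights = c(0.2, 6),
                                      widths = c(0.5, 8),
                                      baseline_type = c("straight", "arc", "gap"),
                                      duplicate_nodule_prob = 0,
                                      seed = 1L) {
  baseline_type <- match.arg(baseline_type)
  if (any(heights <= 0) || any(widths <= 0))
    stop("fixture error: protrusion heights and widths must be > 0")
  set.seed(seed)
  foci <- vector("list", n_foci)

  if (baseline_type %in% c("straight", "gap")) {
    gap_w <- 6
    slot_w <- diff(widths) + widths[1] + 4
    x_left <- -2
    x_right <- x_left + n_foci * slot_w + 2
    for (i in seq_len(n_foci)) {
      h <- stats::runif(1, heights[1], heights[2])
      w <- stats::runif(1, widths[1], widths[2])
      x0 <- x_left + 2 + (i - 1) * slot_w
      foci[[i]] <- list(polygon = .straight_protrusion(x0, h, w),
                        true_r = h, true_w = w)
    }
    if (baseline_type == "gap") {
      # capsule absent over a span beyond the protrusions; the imputed
      # chord is collinear with the rest of the straight baseline
      pts <- rbind(c(x_left, 0), c(x_right, 0),
                   c(x_right + 1, 0), c(x_right + 2, 0),
                   c(x_right + 2 + gap_w, 0), c(x_right + 3 + gap_w, 0))
      base <- capsule_baseline(pts, gap_spans = list(c(4, 5)))
    } else {
      base <- capsule_baseline(rbind(c(x_left, 0), c(x_right, 0)))
    }
  } else {
    # clockwise arc of a circle of radius R: tangent direction clockwise
    # makes the outward (away-from-center) side the left side
    R <- 20
    nv <- 240
    th <- seq(2.4, -2.4, length.out = nv)
    pts <- cbind(R * cos(th), R * sin(th))
    base <- capsule_baseline(pts)
    seg_pick <- sort(sample(seq_len(nv - 1), n_foci))
    for (i in seq_len(n_foci)) {
      j <- seg_pick[i]
      a <- pts[j, ]; b <- pts[j + 1, ]
      mid <- (a + b) / 2
      dir <- (b - a) / sqrt(sum((b - a)^2))
      nrm <- c(-dir[2], dir[1])            # left normal = outward
      h <- stats::runif(1, heights[1], min(heights[2], 3))
      apex <- mid + h * nrm
      foci[[i]] <- list(polygon = rbind(a, apex, b),
                        true_r = h, true_w = sqrt(sum((b - a)^2)))
    }
  }

  ids <- character(n_foci)
  for (i in seq_len(n_foci)) {
    ids[i] <- if (i > 1 && stats::runif(1) < duplicate_nodule_prob)
      ids[i - 1] else paste0("N", i)
    foci[[i]]$nodule_id <- ids[i]
    foci[[i]]$true_shape <- classify_shape(foci[[i]]$true_r, foci[[i]]$true_w)
    .validate_simple_polygon(foci[[i]]$polygon)
  }
  structure(list(baseline = base, foci = foci,
                 expected_focus_count = length(unique(ids)),
                 baseline_type = baseline_type, seed = seed),
            class = "geometry_fixture")
}

#' Write / read a geometry fixture as WKT + JSON manifest
#'
#' The baseline is stored as a `LINESTRING`, each focus contour as a
#' `POLYGON` (one WKT per line of `contours.wkt`), and nodule identities,
#' gap spans and ground-truth measurements in `manifest.json`.
#'
#' @param fixture a `geometry_fixture`.
#' @param dir output directory (created if absent).
#' @return `write_geometry_fixture` invisibly returns `dir`;
#'   `read_geometry_fixture` returns a `geometry_fixture`.
#' @export
write_geometry_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- c(wkt_linestring(fixture$baseline$points),
             vapply(fixture$foci, function(f) wkt_polygon(f$polygon),
                    character(1)))
  writeLines(lines, file.path(dir, "contours.wkt"))
  manifest <- list(
    gap_spans = fixture$baseline$gap_spans,
    baseline_type = fixture$baseline_type,
    expected_focus_count = fixture$expected_focus_count,
    foci = lapply(fixture$foci, function(f)
      list(nodule_id = f$nodule_id, true_r = f$true_r,
           true_w = f$true_w, true_shape = f$true_shape))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_geometry_fixture
#' @export
read_geometry_fixture <- function(dir) {
  lines <- readLines(file.path(dir, "contours.wkt"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  geoms <- lapply(lines, parse_wkt)
  gaps <- if (is.null(man$gap_spans)) NULL else
    lapply(man$gap_spans, function(sp) as.integer(unlist(sp)))
  base <- capsule_baseline(geoms[[1]]$points, gap_spans = gaps)
  foci <- lapply(seq_along(man$foci), function(i) {
    f <- man$foci[[i]]
    list(polygon = geoms[[i + 1]]$points, nodule_id = f$nodule_id,
         true_r = f$true_r, true_w = f$true_w, true_shape = f$true_shape)
  })
  structure(list(baseline = base, foci = foci,
                 expected_focus_count = man$expected_focus_count,
                 baseline_type = man$baseline_type, seed = NA),
            class = "geometry_fixture")
}
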