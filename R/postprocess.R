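#' Maximum Von Mises strain over tissue elements
#'
#' The reported quantity of every simulation case: the maximum equivalent
#' strain over TISSUE elements only (probe-interior strains are excluded),
#' with the centroid location of the argmax element. Ties are broken by the
#' smallest element index so results are deterministic.
#'
#' @param field a `"strain_field"`.
#' @param mesh the mesh the field was computed on (used for centroids when
#'   the field lacks them).
#' @return list with `value`, `location` (length-3, um), `element` (index).
#' @export
max_tissue_strain <- function(field, mesh = NULL) {
  stopifnot(inherits(field, "strain_field"))
  tis <- which(field$region == "tissue")
  if (!length(tis)) stop("no tissue elements in strain field")
  vm <- field$von_mises[tis]
  k <- tis[which.max(vm)]   # which.max returns the first maximum
  cents <- if (!is.null(field$centroids)) field$centroids else
    element_centroids(mesh)
  list(value = field$von_mises[k], location = cents[k, ], element = k)
}

#' Classify a maximum-strain location along the probe axis
#'
#' Thirds-based rule over the embedded length: `"top"` if the axial (y)
#' coordinate lies in the upper third of the embed depth, `"tip"` if in the
#' lower third (or below the tip), `"mid"` otherwise. The raw coordinates
#' are always reported alongside the class so the rule is auditable.
#'
#' @param location length-3 coordinates, um.
#' @param spec the [domain_spec()].
#' @return `"tip"`, `"mid"` or `"top"`.
#' @export
classify_max_location <- function(location, spec) {
  stopifnot(inherits(spec, "domain_spec"))
  y <- location[2]
  if (y < spec$embed_depth / 3) "top"
  else if (y > 2 * spec$embed_depth / 3) "tip"
  else "mid"
}

#' Normalize a strain value against a baseline case
#'
#' @param value strain value.
#' @param baseline baseline strain (must be positive), typically the
#'   stiff-probe maximum at the same displacement.
#' @return `value / baseline`.
#' @export
normalize_to_baseline <- function(value, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive")
  value / baseline
}

#' Percent reduction relative to a baseline
#'
#' @param value strain value.
#' @param baseline baseline strain (positive).
#' @return `100 * (1 - value/baseline)`, percent.
#' @export
percent_reduction <- function(value, baseline) {
  100 * (1 - normalize_to_baseline(value, baseline))
}

#' Strain-versus-distance profile away from the probe
#'
#' Samples the Von Mises field along a line perpendicular to the probe
#' thickness face (+z direction) at one of three section heights: `"tip"`
#' (probe tip level), `"mid"` (half the embedded length), `"top"` (tissue
#' surface level). Elements whose extent contains the sampling line are
#' binned by distance from the probe surface; each bin reports the maximum
#' tissue Von Mises strain among elements overlapping it. For the `mid` and
#' `top` sections sampling starts at 62.5 um from the probe axial axis.
#'
#' @param field a `"strain_field"`.
#' @param mesh the `"hex_mesh"` (must carry its `spec`).
#' @param section `"tip"`, `"mid"` or `"top"`.
#' @param max_distance profile extent from the probe surface, um (default
#'   300; truncated with a warning at the tissue boundary).
#' @param bin_width sampling bin width, um (default 5).
#' @return object of class `"strain_profile"`: data.frame with `distance`
#'   (bin centre, um from the probe thickness face) and `von_mises`.
#' @export
strain_profile <- function(field, mesh, section = c("tip", "mid", "top"),
                           max_distance = 300, bin_width = 5) {
  section <- match.arg(section)
  stopifnot(inherits(field, "strain_field"), inherits(mesh, "hex_mesh"))
  spec <- mesh$spec
  if (is.null(spec)) stop("mesh carries no domain_spec; cannot locate sections")
  ht <- spec$probe_thickness / 2
  y0 <- switch(section, tip = spec$embed_depth, mid = spec$embed_depth / 2,
               top = 0)
  avail <- spec$tissue_length / 2 - ht
  if (max_distance > avail) {
    warning("max_distance truncated to the tissue boundary (", avail, " um)")
    max_distance <- avail
  }
  start <- if (section == "tip") 0 else 62.5 - ht

  n <- mesh$nodes; e <- mesh$elements
  # element bounding extents (axis-aligned grid, so min/max of corner nodes)
  xr <- cbind(pmin(n[e[, 1], 1], n[e[, 7], 1]), pmax(n[e[, 1], 1], n[e[, 7], 1]))
  yr <- cbind(pmin(n[e[, 1], 2], n[e[, 7], 2]), pmax(n[e[, 1], 2], n[e[, 7], 2]))
  zr <- cbind(pmin(n[e[, 1], 3], n[e[, 7], 3]), pmax(n[e[, 1], 3], n[e[, 7], 3]))
  tol <- 1e-9 * spec$tissue_depth
  on_line <- field$region == "tissue" &
    xr[, 1] <= tol & xr[, 2] >= -tol &            # x-range contains 0
    yr[, 1] <= y0 + tol & yr[, 2] >= y0 - tol &   # y-range contains y0
    zr[, 1] >= ht - tol                           # +z side of the probe
  cand <- which(on_line)
  if (!length(cand)) stop("no tissue elements intersect the sampling line")

  edges <- seq(start, max_distance, by = bin_width)
  if (edges[length(edges)] < max_distance) edges <- c(edges, max_distance)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  dlo <- zr[cand, 1] - ht; dhi <- zr[cand, 2] - ht
  vm <- field$von_mises[cand]
  val <- vapply(seq_along(lo), function(b) {
    inb <- dlo < hi[b] - tol & dhi > lo[b] + tol
    if (any(inb)) max(vm[inb]) else NA_real_
  }, 1.0)
  keep <- !is.na(val)
  out <- data.frame(distance = ((lo + hi) / 2)[keep], von_mises = val[keep])
  structure(out, class = c("strain_profile", "data.frame"),
            section = section, bin_width = bin_width)
}

#' Distance over which a strain profile decays
#'
#' First sampled distance at which the profile falls below
#' `threshold_fraction` times its first (probe-adjacent) value.
#'
#' @param profile a `"strain_profile"` (or data.frame with `distance`,
#'   `von_mises`).
#' @param threshold_fraction fraction of the first value, in (0, 1]
#'   (default 0.01).
#' @return list with `distance` (um) and `reached` (FALSE if the profile
#'   never drops below the threshold, in which case `distance` is the last
#'   sampled distance).
#' @export
decay_span <- function(profile, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  d <- profile$distance; v <- profile$von_mises
  stopifnot(length(d) >= 1, !is.unsorted(d, strictly = TRUE))
  thr <- threshold_fraction * v[1]
  below <- which(v < thr | (threshold_fraction == 1 & v <= thr))
  if (threshold_fraction == 1)
    return(list(distance = d[1], reached = TRUE))
  if (length(below)) list(distance = d[below[1]], reached = TRUE)
  else list(distance = d[length(d)], reached = FALSE)
}
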