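#' Probe-in-tissue domain specification
#'
#' Parametric description of the simulated domain: a rectangular probe shank
#' embedded in a brain-tissue block. Coordinates: origin at the centre of the
#' tissue top surface, +y downward along the probe axis, +x the tangential
#' displacement direction (across the probe width), +z across the probe
#' thickness. All lengths in micrometres.
#'
#' The probe top face is flush with the tissue top surface and the probe is
#' embedded to `embed_depth` (defaults to the probe length, so the tip sits
#' at y = `probe_length`).
#'
#' @param probe_length probe shank length, um (default 1125).
#' @param probe_width probe width (x direction), um (default 125).
#' @param probe_thickness probe thickness (z direction), um (default 25).
#' @param tissue_width tissue extent along x, um (default 1500).
#' @param tissue_length tissue extent along z, um (default 1500).
#' @param tissue_depth tissue extent along y, um (default 1500).
#' @param embed_depth axial distance from the tissue top surface to the probe
#'   tip, um. Defaults to `probe_length` (fully embedded, top face flush).
#' @return object of class `"domain_spec"`.
#' @export
#' @examples
#' domain_spec()                      # stiff-probe geometry (25 um thick)
#' domain_spec(probe_thickness = 63)  # compliant-probe geometry
domain_spec <- function(probe_length = 1125, probe_width = 125,
                        probe_thickness = 25, tissue_width = 1500,
                        tissue_length = 1500, tissue_depth = 1500,
                        embed_depth = probe_length) {
  dims <- c(probe_length = probe_length, probe_width = probe_width,
            probe_thickness = probe_thickness, tissue_width = tissue_width,
            tissue_length = tissue_length, tissue_depth = tissue_depth,
            embed_depth = embed_depth)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all domain dimensions must be positive and finite")
  if (probe_width >= tissue_width)
    stop("probe width (", probe_width, " um) must be strictly inside the tissue width (",
         tissue_width, " um)")
  if (probe_thickness >= tissue_length)
    stop("probe thickness (", probe_thickness,
         " um) must be strictly inside the tissue length (", tissue_length, " um)")
  if (embed_depth > tissue_depth)
    stop("embed depth exceeds tissue depth")
  if (embed_depth != probe_length)
    stop("partial embedment unsupported: embed_depth must equal probe_length ",
         "(probe top face lies on the tissue top surface)")
  structure(as.list(dims), class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("<domain_spec> probe %g x %g x %g um in tissue %g x %g x %g um, tip at y = %g um\n",
              x$probe_length, x$probe_width, x$probe_thickness,
              x$tissue_width, x$tissue_length, x$tissue_depth, x$embed_depth))
  invisible(x)
}

#' Graded structured-mesh parameters
#'
#' Controls the tensor-product grid: elements are smallest (`h_near`) at the
#' probe--tissue interfaces and grow geometrically (`ratio`) away from them up
#' to `h_max`. The probe thickness is divided into at least
#' `n_through_thickness` elements (more if `h_near` demands it). Meshing is
#' fully deterministic: identical parameters give a bit-identical mesh.
#'
#' @param h_near near-interface element size, um.
#' @param ratio geometric growth ratio of element size away from the probe
#'   (>= 1).
#' @param h_max far-field element size cap, um.
#' @param n_through_thickness minimum element count through the probe
#'   thickness (>= 3).
#' @return object of class `"mesh_params"`.
#' @export
mesh_params <- function(h_near = 4, ratio = 1.3, h_max = 60,
                        n_through_thickness = 3) {
  stopifnot(is.numeric(h_near), h_near > 0, is.finite(h_near),
            is.numeric(ratio), is.finite(ratio),
            is.numeric(h_max), h_max >= h_near,
            n_through_thickness >= 3)
  if (ratio < 1) stop("grading ratio must be >= 1")
  if (h_max / h_near > 20)
    stop("h_max/h_near = ", h_max / h_near,
         " exceeds the element aspect-ratio bound of 20")
  structure(list(h_near = h_near, ratio = ratio, h_max = h_max,
                 n_through_thickness = as.integer(n_through_thickness)),
            class = "mesh_params")
}

# 1D graded node line from a to b. First element ~ h0 at the refined side(s),
# growing by `ratio` up to hmax; sizes rescaled to fit [a, b] exactly.
graded_line <- function(a, b, h0, ratio, hmax,
                        side = c("start", "end", "both", "uniform")) {
  side <- match.arg(side)
  L <- b - a
  stopifnot(L > 0)
  one_sided <- function(len) {
    sizes <- numeric(0)
    s <- h0
    tot <- 0
    while (tot < len) {
      sizes <- c(sizes, s)
      tot <- tot + s
      s <- min(s * ratio, hmax)
    }
    sizes * (len / sum(sizes))
  }
  sizes <- switch(side,
    start = one_sided(L),
    end = rev(one_sided(L)),
    both = {
      half <- one_sided(L / 2)
      c(half, rev(half))
    },
    uniform = {
      n <- max(1L, round(L / h0))
      rep(L / n, n)
    })
  a + c(0, cumsum(sizes))
}

# Tensor-product hex mesh from grid lines. Nodes ordered x-fastest, then y,
# then z; elements in the same order. Connectivity uses the standard hex8
# node ordering (bottom z-face counterclockwise, then top).
hex_grid_mesh <- function(xs, ys, zs) {
  stopifnot(length(xs) >= 2, length(ys) >= 2, length(zs) >= 2,
            !is.unsorted(xs, strictly = TRUE),
            !is.unsorted(ys, strictly = TRUE),
            !is.unsorted(zs, strictly = TRUE))
  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nxy <- (nx + 1L) * (ny + 1L)
  nid <- function(i, j, k) i + (j - 1L) * (nx + 1L) + (k - 1L) * nxy
  idx <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                     KEEP.OUT.ATTRS = FALSE)
  i <- idx$i; j <- idx$j; k <- idx$k
  elements <- cbind(nid(i,      j,      k),
                    nid(i + 1L, j,      k),
                    nid(i + 1L, j + 1L, k),
                    nid(i,      j + 1L, k),
                    nid(i,      j,      k + 1L),
                    nid(i + 1L, j,      k + 1L),
                    nid(i + 1L, j + 1L, k + 1L),
                    nid(i,      j + 1L, k + 1L))
  storage.mode(elements) <- "integer"
  structure(list(nodes = nodes, elements = elements,
                 region = rep("tissue", nrow(elements)),
                 grid = list(xs = xs, ys = ys, zs = zs),
                 node_sets = list()),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hex8 elements (%d probe, %d tissue)\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$region == "probe"), sum(x$region == "tissue")))
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Generate the graded hexahedral probe-in-tissue mesh
#'
#' Builds a conforming structured mesh of the full tissue box with the probe
#' volume tagged as a separate material region. Probe and tissue share the
#' interface nodes, which realises bonded contact (no slip or separation).
#' Grid lines are placed on every probe boundary so the interface is resolved
#' exactly.
#'
#' Under tangential (x) loading of the centred probe the solution is an even
#' function of x in its x component (odd in y, z components) and even in z
#' except for the odd z component, so the quarter domain x >= 0, z >= 0 with
#' `u_y = u_z = 0` on the x = 0 plane and `u_z = 0` on the z = 0 plane
#' reproduces the full solution at a quarter of the cost.
#' `symmetry = "quarter"` builds that quarter mesh on exactly the grid lines
#' of the corresponding full mesh (so results are comparable line by line);
#' [run_case()] applies the symmetry-plane constraints automatically.
#'
#' @param spec a [domain_spec()].
#' @param params a [mesh_params()].
#' @param monitor_offset distance of the four monitoring points from the
#'   probe--tissue interface, um (default 10).
#' @param symmetry `"none"` (full domain) or `"quarter"` (x >= 0, z >= 0
#'   with symmetry-plane node sets `sym_x0`, `sym_z0`).
#' @return object of class `"hex_mesh"` with fields `nodes` (N x 3, um),
#'   `elements` (M x 8, 1-based), `region` (per element, `"probe"` or
#'   `"tissue"`), and `node_sets` (see [extract_node_sets()]).
#' @export
#' @examples
#' m <- generate_hex_mesh(domain_spec(), mesh_params(h_near = 12, ratio = 1.5,
#'                                                   h_max = 150))
#' m
generate_hex_mesh <- function(spec, params, monitor_offset = 10,
                              symmetry = c("none", "quarter")) {
  stopifnot(inherits(spec, "domain_spec"), inherits(params, "mesh_params"))
  symmetry <- match.arg(symmetry)
  h0 <- params$h_near; r <- params$ratio; hm <- params$h_max
  if (h0 > spec$probe_thickness)
    stop("near-interface element size (", h0,
         " um) exceeds the probe thickness (", spec$probe_thickness, " um)")
  hw <- spec$probe_width / 2
  ht <- spec$probe_thickness / 2
  # through-thickness count rounded up to even so the z = 0 plane is a grid
  # plane in both the full and the quarter mesh
  nt <- max(params$n_through_thickness,
            as.integer(ceiling(spec$probe_thickness / h0)))
  nt <- 2L * as.integer(ceiling(nt / 2))
  half_width <- graded_line(0, hw, h0, r, hm, "end")
  outer_x <- graded_line(hw, spec$tissue_width / 2, h0, r, hm, "start")
  outer_z <- graded_line(ht, spec$tissue_length / 2, h0, r, hm, "start")
  ys <- c(graded_line(0, spec$embed_depth, h0, r, hm, "both"),
          graded_line(spec$embed_depth, spec$tissue_depth, h0, r, hm,
                      "start")[-1])
  if (symmetry == "none") {
    xs <- c(-rev(outer_x), -rev(half_width)[-1], half_width[-1], outer_x[-1])
    zs <- c(-rev(outer_z), seq(-ht, ht, length.out = nt + 1L)[-1],
            outer_z[-1])
  } else {
    xs <- c(half_width, outer_x[-1])
    zs <- c(seq(0, ht, length.out = nt / 2L + 1L), outer_z[-1])
  }
  mesh <- hex_grid_mesh(xs, ys, zs)

  cx <- element_centroid_coord(xs)
  cy <- element_centroid_coord(ys)
  cz <- element_centroid_coord(zs)
  cent <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  inside <- abs(cent$x) < hw & cent$y < spec$embed_depth & abs(cent$z) < ht
  mesh$region <- ifelse(inside, "probe", "tissue")
  mesh$spec <- spec
  mesh$params <- params
  mesh$symmetry <- symmetry
  mesh$node_sets <- extract_node_sets(mesh, spec,
                                      monitor_offset = monitor_offset)
  mesh
}

element_centroid_coord <- function(lines) {
  (lines[-length(lines)] + lines[-1]) / 2
}

#' Named node sets for boundary conditions and monitoring
#'
#' Extracts the sets the solver and the mesh-sensitivity study need:
#' \describe{
#'   \item{bottom_edges}{nodes on the four perimeter edges of the tissue
#'     bottom face (the fixed support).}
#'   \item{probe_top_face}{probe nodes on the tissue top-surface plane (where
#'     the tangential displacement is prescribed).}
#'   \item{interface}{nodes shared by probe and tissue elements (the bonded
#'     contact surface).}
#'   \item{monitor_1..monitor_4}{nearest tissue nodes to four fixed physical
#'     points: two `monitor_offset` um off the tip interface, two
#'     `monitor_offset` um off the top interface.}
#' }
#'
#' @param mesh a `"hex_mesh"` whose grid matches `spec`.
#' @param spec the [domain_spec()] the mesh was generated from.
#' @param monitor_offset monitoring-point offset from the interface, um.
#' @param monitor_points optional 4 x 3 matrix of physical monitoring points
#'   overriding the defaults.
#' @return named list of integer node-index vectors.
#' @export
extract_node_sets <- function(mesh, spec, monitor_offset = 10,
                              monitor_points = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(spec, "domain_spec"))
  nodes <- mesh$nodes
  quarter <- identical(mesh$symmetry, "quarter")
  tol <- 1e-8 * max(spec$tissue_width, spec$tissue_depth)
  on_bottom <- abs(nodes[, 2] - spec$tissue_depth) < tol
  on_rim <- abs(abs(nodes[, 1]) - spec$tissue_width / 2) < tol |
            abs(abs(nodes[, 3]) - spec$tissue_length / 2) < tol
  bottom_edges <- which(on_bottom & on_rim)

  hw <- spec$probe_width / 2
  ht <- spec$probe_thickness / 2
  probe_top_face <- which(abs(nodes[, 2]) < tol &
                          nodes[, 1] >= -hw - tol & nodes[, 1] <= hw + tol &
                          nodes[, 3] >= -ht - tol & nodes[, 3] <= ht + tol)

  probe_nodes <- unique(as.vector(mesh$elements[mesh$region == "probe", ,
                                                drop = FALSE]))
  tissue_nodes <- unique(as.vector(mesh$elements[mesh$region == "tissue", ,
                                                 drop = FALSE]))
  interface <- intersect(probe_nodes, tissue_nodes)

  if (is.null(monitor_points)) {
    d <- monitor_offset
    monitor_points <- rbind(
      c(0, spec$embed_depth + d, 0),        # below the tip, on the axis
      c(0, spec$embed_depth - d, ht + d),   # beside the tip thickness face
      c(0, d, ht + d),                      # near the top interface, +z side
      c(0, d, -(ht + d)))                   # near the top interface, -z side
  }
  stopifnot(is.matrix(monitor_points), ncol(monitor_points) == 3)
  if (quarter) {
    # the solution is mirror-(anti)symmetric, so monitoring points reflect
    # into the retained quadrant with identical Von Mises values
    monitor_points[, 1] <- abs(monitor_points[, 1])
    monitor_points[, 3] <- abs(monitor_points[, 3])
  }
  nearest_tissue_node <- function(p) {
    d2 <- (nodes[tissue_nodes, 1] - p[1])^2 +
          (nodes[tissue_nodes, 2] - p[2])^2 +
          (nodes[tissue_nodes, 3] - p[3])^2
    tissue_nodes[which.min(d2)]
  }
  monitors <- apply(monitor_points, 1, nearest_tissue_node)

  sets <- c(list(bottom_edges = bottom_edges,
                 probe_top_face = probe_top_face,
                 interface = interface),
            stats::setNames(as.list(monitors),
                            paste0("monitor_", seq_along(monitors))))
  if (quarter) {
    sets$sym_x0 <- which(abs(nodes[, 1]) < tol)
    sets$sym_z0 <- which(abs(nodes[, 3]) < tol)
  }
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty))
    stop("empty node set(s): ", paste(empty, collapse = ", "),
         " (mesh/spec mismatch)")
  sets
}

#' Element volumes and Jacobian check
#'
#' @param mesh a `"hex_mesh"`.
#' @return numeric vector of element volumes, um^3.
#' @export
element_volumes <- function(mesh) {
  element_volumes_cpp(mesh$nodes, mesh$elements)
}

#' Minimum quadrature-point Jacobian determinant per element
#'
#' Positive everywhere for a valid (non-inverted) mesh.
#'
#' @param mesh a `"hex_mesh"`.
#' @return numeric vector, one minimum detJ per element.
#' @export
min_jacobians <- function(mesh) {
  min_jacobians_cpp(mesh$nodes, mesh$elements)
}
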