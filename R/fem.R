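#' Element stiffness matrix for an 8-node hexahedron
#'
#' Trilinear displacement interpolation, 2x2x2 Gauss quadrature. With
#' `bbar = TRUE` the volumetric strain-displacement rows are replaced by
#' their element average (mean-dilatation B-bar), the standard cure for
#' volumetric locking of trilinear hexes at near-incompressible Poisson
#' ratios such as brain tissue's 0.45.
#'
#' @param coords 8 x 3 node coordinates, um, in standard hex8 ordering.
#' @param material a [material()].
#' @param bbar use the B-bar volumetric treatment (default `TRUE`).
#' @return 24 x 24 symmetric positive-semidefinite stiffness matrix (dof
#'   order: node-major x, y, z).
#' @export
element_stiffness <- function(coords, material, bbar = TRUE) {
  stopifnot(inherits(material, "material"))
  hex8_stiffness_cpp(coords, material$lambda, material$mu, bbar)
}

#' Assemble the global linear-elastic stiffness system
#'
#' Sums element stiffness contributions into a sparse symmetric global
#' matrix, stored as lower-triangle triplets. Nodes carry three dofs
#' (x, y, z), numbered `3*(node-1) + 1..3`.
#'
#' @param mesh a `"hex_mesh"` with per-element region tags.
#' @param materials named list mapping each region tag present in the mesh
#'   (`"probe"`, `"tissue"`) to a [material()].
#' @param bbar use B-bar elements (default `TRUE`).
#' @return object of class `"linear_system"` with the triplet stiffness, dof
#'   count, and empty constraint set.
#' @export
assemble <- function(mesh, materials, bbar = TRUE) {
  stopifnot(inherits(mesh, "hex_mesh"))
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("no material given for region(s): ", paste(missing, collapse = ", "))
  lambda <- vapply(materials, function(m) m$lambda, 1.0)[mesh$region]
  mu <- vapply(materials, function(m) m$mu, 1.0)[mesh$region]
  trip <- assemble_triplets_cpp(mesh$nodes, mesh$elements, lambda, mu, bbar)
  structure(list(triplets = trip, ndof = 3L * nrow(mesh$nodes),
                 mesh = mesh, materials = materials,
                 constrained_dofs = integer(0),
                 constrained_values = numeric(0)),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("<linear_system> %d dofs, %d stored triplets, %d constrained dofs\n",
              x$ndof, length(x$triplets$x), length(x$constrained_dofs)))
  invisible(x)
}

#' Global stiffness as a sparse symmetric Matrix
#'
#' @param system a `"linear_system"` from [assemble()].
#' @return a `dsCMatrix` (ndof x ndof).
#' @export
stiffness_matrix <- function(system) {
  t <- system$triplets
  Matrix::sparseMatrix(i = t$i, j = t$j, x = t$x,
                       dims = c(system$ndof, system$ndof), symmetric = TRUE)
}

# dof indices (1-based) for a set of nodes; comps subset of 1:3
node_dofs <- function(nodes, comps = 1:3) {
  as.vector(t(outer(3L * (as.integer(nodes) - 1L), as.integer(comps), `+`)))
}

# low-level Dirichlet constraint: prescribe values at global dof indices
constrain_dofs <- function(system, dofs, values) {
  stopifnot(inherits(system, "linear_system"),
            length(dofs) == length(values))
  dup <- intersect(system$constrained_dofs, dofs)
  if (length(dup)) {
    keep <- match(dup, system$constrained_dofs)
    newv <- values[match(dup, dofs)]
    if (any(abs(system$constrained_values[keep] - newv) > 0))
      stop("conflicting constraint on dof(s): ",
           paste(utils::head(dup), collapse = ", "))
  }
  fresh <- !dofs %in% system$constrained_dofs
  system$constrained_dofs <- c(system$constrained_dofs, dofs[fresh])
  system$constrained_values <- c(system$constrained_values, values[fresh])
  system
}

#' Apply the micromotion boundary conditions
#'
#' Realises the loading of the probe--tissue model: the four perimeter edges
#' of the tissue bottom face are pinned in all three components, and a
#' tangential displacement `d` is prescribed (single component, `direction`)
#' on every node of the probe top face, leaving the other two components
#' free. Micromotion displacements discussed for cortical implants span
#' roughly 1--60 um; values outside `[0, 60]` trigger a warning.
#'
#' @param system a `"linear_system"`.
#' @param fixed node indices pinned in all components (value 0).
#' @param prescribed node indices receiving the displacement.
#' @param d prescribed displacement, um.
#' @param direction `"x"`, `"y"` or `"z"` (default `"x"`, tangential).
#' @return the system with constraints recorded.
#' @export
apply_boundary_conditions <- function(system, fixed, prescribed, d,
                                      direction = "x") {
  stopifnot(inherits(system, "linear_system"))
  if (!length(fixed) || !length(prescribed))
    stop("fixed and prescribed node sets must be non-empty")
  if (length(intersect(fixed, prescribed)))
    stop("fixed and prescribed node sets overlap")
  if (d < 0 || d > 60)
    warning("displacement d = ", d,
            " um lies outside the 0-60 um micromotion range")
  comp <- match(match.arg(direction, c("x", "y", "z")), c("x", "y", "z"))
  system <- constrain_dofs(system, node_dofs(fixed, 1:3),
                           rep(0, 3L * length(fixed)))
  constrain_dofs(system, node_dofs(prescribed, comp),
                 rep(d, length(prescribed)))
}

#' Solve the constrained elasticity system
#'
#' Eliminates the prescribed dofs, solves the reduced symmetric
#' positive-definite system (sparse Cholesky by default, Jacobi-preconditioned
#' conjugate gradients as the iterative path), and reports the relative
#' residual of the full system.
#'
#' @param system a constrained `"linear_system"`.
#' @param method `"direct"` (sparse Cholesky, deterministic) or `"cg"`.
#' @param tol relative residual tolerance (default 1e-8); the CG path iterates
#'   to it, the direct path verifies against it.
#' @param maxit CG iteration cap.
#' @return object of class `"displacement_field"`: list with `U` (N x 3 nodal
#'   displacements, um), `residual` (relative), `method`.
#' @export
solve_system <- function(system, method = c("direct", "cg"), tol = 1e-8,
                         maxit = 20000L) {
  method <- match.arg(method)
  stopifnot(inherits(system, "linear_system"))
  if (!length(system$constrained_dofs))
    stop("system has no constraints; the unconstrained problem is singular")
  ndof <- system$ndof
  map <- integer(ndof)
  free <- setdiff(seq_len(ndof), system$constrained_dofs)
  map[free] <- seq_along(free)
  uc <- numeric(ndof)
  uc[system$constrained_dofs] <- system$constrained_values

  red <- reduce_system_cpp(system$triplets$i, system$triplets$j,
                           system$triplets$x, map, uc)
  Kff <- Matrix::sparseMatrix(i = red$i, j = red$j, x = red$x,
                              dims = c(red$nfree, red$nfree),
                              symmetric = TRUE)
  rhs <- red$rhs
  uf <- if (method == "direct") {
    ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    as.vector(Matrix::solve(ch, rhs, system = "A"))
  } else {
    cg_solve(Kff, rhs, tol = tol, maxit = maxit)
  }
  u <- uc
  u[free] <- uf

  f <- triplet_symm_matvec_cpp(system$triplets$i, system$triplets$j,
                               system$triplets$x, u, ndof)
  rhs_norm <- sqrt(sum(rhs^2))
  resid <- if (rhs_norm > 0) sqrt(sum(f[free]^2)) / rhs_norm else
    sqrt(sum(f[free]^2))
  if (method == "direct" && resid > 1e-6)
    warning("direct solve residual ", format(resid), " is unexpectedly large")
  structure(list(U = matrix(u, ncol = 3, byrow = TRUE),
                 residual = resid, method = method,
                 reactions = matrix(f, ncol = 3, byrow = TRUE)),
            class = "displacement_field")
}

# Jacobi-preconditioned conjugate gradients on a dsCMatrix
cg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bnorm <= tol) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  stop("CG did not converge in ", maxit, " iterations; achieved residual ",
       format(sqrt(sum(r^2)) / bnorm))
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d nodes, |u|_max = %g um, residual = %.3g (%s)\n",
              nrow(x$U), max(abs(x$U)), x$residual, x$method))
  invisible(x)
}

#' Centroid strain tensors and Von Mises equivalent strain
#'
#' Recovers the small-strain tensor \eqn{\epsilon = sym(\nabla u)} at each
#' element centroid and its Von Mises (equivalent elastic) strain. Strains
#' are sampled at centroids without nodal averaging, so maxima are not
#' smoothed.
#'
#' The equivalent strain uses an effective Poisson ratio per element; by
#' default each element uses its own material's ratio (tissue elements 0.45),
#' overridable with `nu_eff`.
#'
#' @param mesh the `"hex_mesh"` the displacements live on.
#' @param u a `"displacement_field"` from [solve_system()], or an N x 3
#'   matrix of nodal displacements.
#' @param materials named region->[material()] list (defaults to the ones
#'   stored on the system that produced `u` being unavailable here, so pass
#'   the same list used in [assemble()]).
#' @param nu_eff optional single effective Poisson ratio applied to all
#'   elements (overrides per-material values).
#' @return object of class `"strain_field"`: list with `tensors` (M x 6,
#'   tensor components xx, yy, zz, xy, yz, zx), `von_mises` (M), `region`,
#'   `centroids` (M x 3, um), `nu_eff` (M).
#' @export
compute_strain_field <- function(mesh, u, materials = NULL, nu_eff = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  U <- if (inherits(u, "displacement_field")) u$U else as.matrix(u)
  stopifnot(nrow(U) == nrow(mesh$nodes), ncol(U) == 3)
  tensors <- centroid_strains_cpp(mesh$nodes, mesh$elements, U)
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  nu_vec <- if (!is.null(nu_eff)) {
    rep(nu_eff, nrow(tensors))
  } else if (!is.null(materials)) {
    vapply(materials, function(m) m$nu, 1.0)[mesh$region]
  } else {
    rep(0, nrow(tensors))
  }
  vm <- von_mises_strain(tensors, nu_vec)
  cents <- element_centroids(mesh)
  structure(list(tensors = tensors, von_mises = vm, region = mesh$region,
                 centroids = cents, nu_eff = nu_vec),
            class = "strain_field")
}

element_centroids <- function(mesh) {
  n <- mesh$nodes
  e <- mesh$elements
  cbind((n[e[, 1], 1] + n[e[, 2], 1] + n[e[, 3], 1] + n[e[, 4], 1] +
         n[e[, 5], 1] + n[e[, 6], 1] + n[e[, 7], 1] + n[e[, 8], 1]) / 8,
        (n[e[, 1], 2] + n[e[, 2], 2] + n[e[, 3], 2] + n[e[, 4], 2] +
         n[e[, 5], 2] + n[e[, 6], 2] + n[e[, 7], 2] + n[e[, 8], 2]) / 8,
        (n[e[, 1], 3] + n[e[, 2], 3] + n[e[, 3], 3] + n[e[, 4], 3] +
         n[e[, 5], 3] + n[e[, 6], 3] + n[e[, 7], 3] + n[e[, 8], 3]) / 8)
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d elements, max Von Mises = %g (tissue max = %g)\n",
              length(x$von_mises), max(x$von_mises),
              max(x$von_mises[x$region == "tissue"])))
  invisible(x)
}

#' Von Mises (equivalent elastic) strain
#'
#' \deqn{\epsilon_{eq} = \frac{1}{1+\nu_{eff}} \sqrt{\tfrac{1}{2}\left[
#'   (\epsilon_1-\epsilon_2)^2 + (\epsilon_2-\epsilon_3)^2 +
#'   (\epsilon_3-\epsilon_1)^2\right]}}
#' over the principal strains, evaluated through the equivalent tensor
#' invariant (no eigendecomposition needed). Zero exactly for hydrostatic
#' states; insensitive to superposed rigid motion.
#'
#' @param tensor either a length-6 vector `(xx, yy, zz, xy, yz, zx)` with
#'   TENSOR shear components, an M x 6 matrix of such rows, or a symmetric
#'   3 x 3 matrix.
#' @param nu_eff effective Poisson ratio(s), in `[0, 0.5]` (postprocessing
#'   only, so 0.5 is allowed). Recycled over rows.
#' @return numeric vector of equivalent strains (dimensionless).
#' @export
#' @examples
#' von_mises_strain(c(1e-3, 0, 0, 0, 0, 0), nu_eff = 0)  # uniaxial: 1e-3
von_mises_strain <- function(tensor, nu_eff = 0) {
  if (is.matrix(tensor) && nrow(tensor) == 3 && ncol(tensor) == 3) {
    if (max(abs(tensor - t(tensor))) > 1e-12 * max(1, max(abs(tensor))))
      stop("strain tensor must be symmetric")
    tensor <- matrix(c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
                       tensor[1, 2], tensor[2, 3], tensor[3, 1]), nrow = 1)
  } else if (!is.matrix(tensor)) {
    stopifnot(length(tensor) == 6)
    tensor <- matrix(tensor, nrow = 1)
  }
  stopifnot(ncol(tensor) == 6)
  if (any(nu_eff < 0 | nu_eff > 0.5))
    stop("nu_eff must lie in [0, 0.5]")
  exx <- tensor[, 1]; eyy <- tensor[, 2]; ezz <- tensor[, 3]
  exy <- tensor[, 4]; eyz <- tensor[, 5]; ezx <- tensor[, 6]
  s <- sqrt(0.5 * ((exx - eyy)^2 + (eyy - ezz)^2 + (ezz - exx)^2) +
            3 * (exy^2 + eyz^2 + ezx^2))
  as.vector(s / (1 + nu_eff))
}

#' Rigid-body modes of a node set
#'
#' Six translation/rotation vectors used by the stiffness null-space checks.
#'
#' @param nodes N x 3 node coordinates.
#' @return (3N) x 6 matrix; columns are the three translations and three
#'   infinitesimal rotations.
#' @export
rigid_body_modes <- function(nodes) {
  N <- nrow(nodes)
  modes <- matrix(0, 3 * N, 6)
  ix <- seq(1, 3 * N, by = 3)
  modes[ix, 1] <- 1
  modes[ix + 1, 2] <- 1
  modes[ix + 2, 3] <- 1
  # rotations about x, y, z
  modes[ix + 1, 4] <- -nodes[, 3]; modes[ix + 2, 4] <- nodes[, 2]
  modes[ix, 5] <- nodes[, 3];      modes[ix + 2, 5] <- -nodes[, 1]
  modes[ix, 6] <- -nodes[, 2];     modes[ix + 1, 6] <- nodes[, 1]
  modes
}
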