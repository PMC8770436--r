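#' Analytic verification fixtures
#'
#' Small elasticity problems with known exact solutions that gate the FEM
#' core before any probe case is trusted: a constant-strain patch test on a
#' distorted mesh, a homogeneous uniaxial block, a slender cantilever checked
#' against Timoshenko beam theory, and a two-material bar in series checked
#' against the exact strain partition. All fixtures are generated
#' deterministically in code.
#'
#' A fixture bundles a mesh, Dirichlet constraints (`dofs`, `values`), the
#' materials per region, and its exact solution (`exact_U` and/or named
#' scalars in `exact`). [run_fixture()] solves it and returns the errors.
#'
#' @name verification_fixtures
NULL

new_fixture <- function(name, mesh, dofs, values, materials, exact_U = NULL,
                        exact = list(), tol = 1e-8, bbar = TRUE) {
  structure(list(name = name, mesh = mesh, dofs = dofs, values = values,
                 materials = materials, exact_U = exact_U, exact = exact,
                 tol = tol, bbar = bbar),
            class = "fem_fixture")
}

#' @export
print.fem_fixture <- function(x, ...) {
  cat(sprintf("<fem_fixture> %s: %d elements, %d constrained dofs, tol = %g\n",
              x$name, nrow(x$mesh$elements), length(x$dofs), x$tol))
  invisible(x)
}

#' Solve a verification fixture and measure its error
#'
#' @param fixture a `"fem_fixture"`.
#' @param method solver path, `"direct"` or `"cg"`.
#' @return list with the solved `u`, the strain `field`,
#'   `max_displacement_error` (absolute, um, against `exact_U` when given),
#'   and any fixture-specific measured quantities.
#' @export
run_fixture <- function(fixture, method = "direct") {
  stopifnot(inherits(fixture, "fem_fixture"))
  sys <- assemble(fixture$mesh, fixture$materials, bbar = fixture$bbar)
  sys <- constrain_dofs(sys, fixture$dofs, fixture$values)
  u <- solve_system(sys, method = method)
  field <- compute_strain_field(fixture$mesh, u,
                                materials = fixture$materials)
  out <- list(u = u, field = field, fixture = fixture)
  if (!is.null(fixture$exact_U))
    out$max_displacement_error <- max(abs(u$U - fixture$exact_U))
  if (!is.null(fixture$exact$reaction)) {
    # total constrained-direction reaction on the loaded dof set
    loaded <- fixture$exact$reaction_dofs
    out$reaction <- sum(u$reactions[cbind((loaded - 1) %/% 3 + 1,
                                          (loaded - 1) %% 3 + 1)])
  }
  out
}

#' Uniaxial homogeneous-strain block
#'
#' A block stretched along x with lateral faces free. Exact solution:
#' `u = (s x, -nu s y, -nu s z)` (homogeneous strain, reproduced exactly by
#' trilinear elements).
#'
#' @param E modulus, MPa.
#' @param nu Poisson ratio.
#' @param stretch imposed axial strain (dimensionless, small).
#' @param n elements per axis (default 4).
#' @param L block edge length, um (default 10).
#' @return a `"fem_fixture"` with `exact_U` and exact strain tensor in
#'   `exact$strain`.
#' @export
uniaxial_block <- function(E, nu, stretch, n = 4, L = 10) {
  lines <- seq(0, L, length.out = n + 1)
  mesh <- hex_grid_mesh(lines, lines, lines)
  nodes <- mesh$nodes
  tol <- 1e-9 * L
  at0 <- which(abs(nodes[, 1]) < tol)
  atL <- which(abs(nodes[, 1] - L) < tol)
  dofs <- c(node_dofs(at0, 1), node_dofs(atL, 1))
  values <- c(rep(0, length(at0)), rep(stretch * L, length(atL)))
  # pin rigid modes consistently with the exact solution (origin corner)
  corner <- which(abs(nodes[, 1]) < tol & abs(nodes[, 2]) < tol &
                  abs(nodes[, 3]) < tol)
  edge <- which(abs(nodes[, 1]) < tol & abs(nodes[, 2] - L) < tol &
                abs(nodes[, 3]) < tol)
  dofs <- c(dofs, node_dofs(corner, 2:3), node_dofs(edge, 3))
  values <- c(values, 0, 0, 0)
  exact_U <- cbind(stretch * nodes[, 1], -nu * stretch * nodes[, 2],
                   -nu * stretch * nodes[, 3])
  new_fixture("uniaxial_block", mesh, dofs, values,
              list(tissue = material("block", E, nu)),
              exact_U = exact_U,
              exact = list(strain = c(stretch, -nu * stretch, -nu * stretch,
                                      0, 0, 0)),
              tol = 1e-10)
}

#' Constant-strain patch test on a distorted mesh
#'
#' A 3x3x3 hex mesh whose interior nodes are displaced by a fixed smooth
#' (deterministic) perturbation; an arbitrary linear displacement field
#' `u = A x + b` is imposed on every boundary node. A convergent element
#' must reproduce the same linear field in the interior and a constant
#' strain tensor in every element, to near machine precision.
#'
#' @param mat a [material()].
#' @param A 3 x 3 displacement-gradient matrix (default: a fixed
#'   non-symmetric gradient with strain magnitude ~1e-3).
#' @param b length-3 offset (default zeros).
#' @param distortion relative interior-node perturbation (default 0.15).
#' @return a `"fem_fixture"`; `exact$strain` holds the constant tensor.
#' @export
patch_test <- function(mat, A = NULL, b = c(0, 0, 0), distortion = 0.15) {
  if (is.null(A))
    A <- matrix(c(1.0,  0.4, -0.3,
                  0.2, -0.7,  0.5,
                 -0.4,  0.1,  0.8) * 1e-3, 3, 3, byrow = TRUE)
  n <- 3
  lines <- seq(0, 1, length.out = n + 1)
  mesh <- hex_grid_mesh(lines, lines, lines)
  nodes <- mesh$nodes
  h <- 1 / n
  interior <- which(nodes[, 1] > 1e-12 & nodes[, 1] < 1 - 1e-12 &
                    nodes[, 2] > 1e-12 & nodes[, 2] < 1 - 1e-12 &
                    nodes[, 3] > 1e-12 & nodes[, 3] < 1 - 1e-12)
  # fixed smooth perturbation: deterministic, keeps Jacobians positive
  p <- nodes[interior, , drop = FALSE]
  mesh$nodes[interior, 1] <- p[, 1] + distortion * h * sin(2.1 * p[, 2] + 0.3) * cos(1.7 * p[, 3])
  mesh$nodes[interior, 2] <- p[, 2] + distortion * h * sin(1.3 * p[, 3] + 1.1) * cos(2.3 * p[, 1])
  mesh$nodes[interior, 3] <- p[, 3] + distortion * h * sin(1.9 * p[, 1] + 0.7) * cos(1.1 * p[, 2])
  nodes <- mesh$nodes
  boundary <- setdiff(seq_len(nrow(nodes)), interior)
  ub <- nodes %*% t(A) + matrix(b, nrow(nodes), 3, byrow = TRUE)
  dofs <- node_dofs(boundary, 1:3)
  values <- as.vector(t(ub[boundary, , drop = FALSE]))
  eps <- (A + t(A)) / 2
  new_fixture("patch_test", mesh, dofs, values,
              list(tissue = mat),
              exact_U = nodes %*% t(A) + matrix(b, nrow(nodes), 3, byrow = TRUE),
              exact = list(strain = c(eps[1, 1], eps[2, 2], eps[3, 3],
                                      eps[1, 2], eps[2, 3], eps[3, 1])),
              tol = 1e-10)
}

#' Slender cantilever with prescribed tip deflection
#'
#' Beam along x, clamped at x = 0, uniform transverse (z) displacement
#' prescribed on the tip face. The reaction is checked against the
#' Timoshenko tip stiffness for an end-loaded cantilever,
#' `k = 1 / (L^3/(3 E I) + L/(kappa G A))` with shear factor
#' `kappa = 5/6`. This verifies the bending behaviour that drives the
#' probe-thickness effect.
#'
#' @param E modulus, MPa.
#' @param nu Poisson ratio.
#' @param dims length-3 `(L, width, thickness)`, um; requires
#'   `L >= 10 * thickness` (warns otherwise).
#' @param tip_displacement prescribed tip deflection, um.
#' @param nx,nt elements along the length / through the thickness (near-unit
#'   element aspect ratio keeps parasitic shear stiffness small).
#' @return a `"fem_fixture"`; `exact$reaction` is the Timoshenko reaction,
#'   MPa um^2 (force in the consistent unit system).
#' @export
cantilever <- function(E, nu, dims = c(250, 25, 12.5), tip_displacement = 1,
                       nx = 80, nt = 4) {
  L <- dims[1]; w <- dims[2]; t <- dims[3]
  if (L < 10 * t) warning("beam is not slender (L < 10 t); the beam-theory ",
                          "reaction check loses accuracy")
  nw <- max(2L, round(nt * w / t))
  mesh <- hex_grid_mesh(seq(0, L, length.out = nx + 1),
                        seq(0, w, length.out = nw + 1),
                        seq(0, t, length.out = nt + 1))
  nodes <- mesh$nodes
  tol <- 1e-9 * L
  clamped <- which(abs(nodes[, 1]) < tol)
  tip <- which(abs(nodes[, 1] - L) < tol)
  dofs <- c(node_dofs(clamped, 1:3), node_dofs(tip, 3))
  values <- c(rep(0, 3 * length(clamped)), rep(tip_displacement, length(tip)))
  I <- w * t^3 / 12
  G <- E / (2 * (1 + nu))
  k <- 1 / (L^3 / (3 * E * I) + L / (5 / 6 * G * w * t))
  new_fixture("cantilever", mesh, dofs, values,
              list(tissue = material("beam", E, nu)),
              exact = list(reaction = k * tip_displacement,
                           reaction_dofs = node_dofs(tip, 3),
                           stiffness = k),
              tol = 0.05)
}

#' Two-material bar in series
#'
#' Two equal-length blocks of moduli `E1`, `E2` bonded in series along x,
#' stretched by prescribed end displacements with `nu = 0` (no Poisson
#' coupling, so the 1D series-spring solution is exact): the strain
#' partition is `eps1/eps2 = E2/E1` and the displacement is piecewise
#' linear. This verifies two-material interface handling, the core of the
#' probe--tissue stiffness mismatch.
#'
#' @param E1,E2 block moduli, MPa.
#' @param stretch overall imposed strain (end displacement / total length).
#' @param n elements per axis per block (default 3).
#' @param L length of EACH block, um (default 10).
#' @return a `"fem_fixture"` with `exact_U` and per-region exact strains in
#'   `exact$strain1`, `exact$strain2`.
#' @export
bimaterial_series <- function(E1, E2, stretch, n = 3, L = 10) {
  xs <- seq(0, 2 * L, length.out = 2 * n + 1)
  yz <- seq(0, L, length.out = n + 1)
  mesh <- hex_grid_mesh(xs, yz, yz)
  cents <- element_centroids(mesh)
  mesh$region <- ifelse(cents[, 1] < L, "block1", "block2")
  nodes <- mesh$nodes
  tol <- 1e-9 * L
  at0 <- which(abs(nodes[, 1]) < tol)
  atL <- which(abs(nodes[, 1] - 2 * L) < tol)
  dofs <- c(node_dofs(at0, 1), node_dofs(atL, 1))
  uend <- stretch * 2 * L
  values <- c(rep(0, length(at0)), rep(uend, length(atL)))
  corner <- which(abs(nodes[, 1]) < tol & abs(nodes[, 2]) < tol &
                  abs(nodes[, 3]) < tol)
  edge <- which(abs(nodes[, 1]) < tol & abs(nodes[, 2] - L) < tol &
                abs(nodes[, 3]) < tol)
  dofs <- c(dofs, node_dofs(corner, 2:3), node_dofs(edge, 3))
  values <- c(values, 0, 0, 0)
  # series springs: sigma continuous, eps_i = sigma/E_i, total elongation uend
  sigma <- uend / (L / E1 + L / E2)
  e1 <- sigma / E1
  e2 <- sigma / E2
  ux <- ifelse(nodes[, 1] <= L + tol, e1 * nodes[, 1],
               e1 * L + e2 * (nodes[, 1] - L))
  exact_U <- cbind(ux, 0, 0)
  new_fixture("bimaterial_series", mesh, dofs, values,
              list(block1 = material("block1", E1, 0),
                   block2 = material("block2", E2, 0)),
              exact_U = exact_U,
              exact = list(strain1 = e1, strain2 = e2, ratio = E2 / E1),
              tol = 1e-8)
}

#' Run all verification fixtures
#'
#' Solves the four analytic fixtures with representative materials and
#' returns a pass/fail summary. These gates precede any probe-case report.
#'
#' @param method solver path.
#' @return data.frame with fixture name, measured error, tolerance, pass.
#' @export
verify_all <- function(method = "direct") {
  cat_ <- material_catalog()
  checks <- list()
  r <- run_fixture(uniaxial_block(E = 6, nu = 0.45, stretch = 1e-3), method)
  checks$uniaxial <- c(error = r$max_displacement_error / 1e-2, tol = 1e-10)
  r <- run_fixture(patch_test(cat_$brain), method)
  checks$patch <- c(error = r$max_displacement_error, tol = 1e-10)
  fx <- cantilever(E = 2.7e3, nu = 0.33)
  r <- run_fixture(fx, method)
  checks$cantilever <- c(error = abs(r$reaction - fx$exact$reaction) /
                           fx$exact$reaction, tol = 0.05)
  fx <- bimaterial_series(E1 = 2e5, E2 = 6, stretch = 1e-3)
  r <- run_fixture(fx, method)
  s <- r$field
  e1 <- mean(s$tensors[s$region == "block1", 1])
  e2 <- mean(s$tensors[s$region == "block2", 1])
  checks$bimaterial <- c(error = abs(e1 / e2 - fx$exact$ratio) /
                           fx$exact$ratio, tol = 1e-8)
  out <- data.frame(fixture = names(checks),
                    error = vapply(checks, `[`, 1.0, 1),
                    tol = vapply(checks, `[`, 1.0, 2))
  out$pass <- out$error <= out$tol
  rownames(out) <- NULL
  out
}
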