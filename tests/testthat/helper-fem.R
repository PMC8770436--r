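# shared helpers: coarse study meshes and memoised case solves so several
# test files can reuse the same solution without re-solving

coarse_mesh_params <- function() {
  mesh_params(h_near = 8, ratio = 1.4, h_max = 100)
}

.case_cache <- new.env(parent = emptyenv())

# coarse quarter-domain solve of a study case, cached across test files
coarse_case <- function(id, keep_field = TRUE) {
  key <- paste0(id, "_", keep_field)
  if (is.null(.case_cache[[key]])) {
    cf <- case_config(id, mesh = coarse_mesh_params())
    .case_cache[[key]] <- run_case(cf, keep_field = keep_field)
  }
  .case_cache[[key]]
}

# independent reference B-matrix (6x24, engineering shear) used by the
# brute-force element-stiffness oracle; mirrors standard textbook formulas,
# written without reference to the package internals
ref_shape_grad <- function(xi, eta, zeta) {
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
              ncol = 3, byrow = TRUE)
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * zeta) / 8
    dN[a, 2] <- s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * zeta) / 8
    dN[a, 3] <- s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta) / 8
  }
  dN
}

# high-order numerical quadrature of the full-integration stiffness integrand
ref_hex_stiffness <- function(coords, E, nu, ngauss = 5) {
  D <- matrix(0, 6, 6)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gl <- pracma::gaussLegendre(ngauss, -1, 1)
  K <- matrix(0, 24, 24)
  for (i in seq_len(ngauss)) for (j in seq_len(ngauss)) for (k in seq_len(ngauss)) {
    dN <- ref_shape_grad(gl$x[i], gl$x[j], gl$x[k])
    J <- t(dN) %*% coords
    dNdx <- dN %*% t(solve(J))
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dNdx[a, 1]
      B[2, c0 + 2] <- dNdx[a, 2]
      B[3, c0 + 3] <- dNdx[a, 3]
      B[4, c0 + 1] <- dNdx[a, 2]; B[4, c0 + 2] <- dNdx[a, 1]
      B[5, c0 + 2] <- dNdx[a, 3]; B[5, c0 + 3] <- dNdx[a, 2]
      B[6, c0 + 1] <- dNdx[a, 3]; B[6, c0 + 3] <- dNdx[a, 1]
    }
    K <- K + gl$w[i] * gl$w[j] * gl$w[k] * det(J) * t(B) %*% D %*% B
  }
  K
}

# unit cube element in standard hex8 node order
unit_cube_coords <- function() {
  matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
           0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
         ncol = 3, byrow = TRUE)
}
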