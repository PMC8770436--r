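test_that("uniaxial block reproduces the homogeneous solution exactly", {
  for (nu in c(0, 0.45)) {
    fx <- uniaxial_block(E = 6, nu = nu, stretch = 1e-3)
    r <- run_fixture(fx)
    expect_lte(r$max_displacement_error, 1e-12)
    # every element carries the exact strain tensor
    expect_equal(r$field$tensors[, "xx"],
                 rep(1e-3, nrow(r$field$tensors)), tolerance = 1e-10)
    expect_equal(r$field$tensors[, "yy"],
                 rep(-nu * 1e-3, nrow(r$field$tensors)), tolerance = 1e-10)
    # Von Mises of the exact tensor via the eigen oracle matches the
    # recovered field value
    Tm <- diag(c(1e-3, -nu * 1e-3, -nu * 1e-3))
    p <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
    ref <- sqrt(0.5 * ((p[1] - p[2])^2 + (p[2] - p[3])^2 +
                       (p[3] - p[1])^2)) / (1 + nu)
    expect_equal(max(r$field$von_mises), ref, tolerance = 1e-9)
  }
})

test_that("patch test passes on a distorted mesh for all catalog materials", {
  for (m in material_catalog()) {
    fx <- patch_test(m)
    expect_true(all(min_jacobians(fx$mesh) > 0))
    r <- run_fixture(fx)
    expect_lte(r$max_displacement_error, 1e-10)
    # constant strain tensor across all elements
    for (k in 1:6)
      expect_equal(r$field$tensors[, k],
                   rep(fx$exact$strain[k], nrow(r$field$tensors)),
                   tolerance = 1e-10)
  }
})

test_that("superposed rigid translation leaves the patch strain unchanged", {
  fx <- patch_test(material("t", 6, 0.45), b = c(0, 0, 0))
  fx_shift <- patch_test(material("t", 6, 0.45), b = c(2, -1, 3))
  s0 <- run_fixture(fx)$field$tensors
  s1 <- run_fixture(fx_shift)$field$tensors
  expect_equal(s0, s1, tolerance = 1e-10)
})

test_that("cantilever reaction matches Timoshenko beam theory", {
  fx <- cantilever(E = 2.7e3, nu = 0.33)
  r <- run_fixture(fx)
  expect_lte(abs(r$reaction - fx$exact$reaction) / fx$exact$reaction, 0.05)
  # halving E halves the reaction exactly (linearity in the modulus)
  fx_half <- cantilever(E = 1.35e3, nu = 0.33)
  r_half <- run_fixture(fx_half)
  expect_equal(r_half$reaction, r$reaction / 2, tolerance = 1e-10)
})

test_that("bending stiffness scales with thickness cubed", {
  # doubling the thickness multiplies the Timoshenko bending stiffness by
  # ~8; the FEM reactions must reproduce that within 10%
  fx1 <- cantilever(E = 2.7e3, nu = 0.33, dims = c(250, 25, 6.25),
                    nx = 80, nt = 4)
  fx2 <- cantilever(E = 2.7e3, nu = 0.33, dims = c(250, 25, 12.5),
                    nx = 80, nt = 4)
  r1 <- run_fixture(fx1)
  r2 <- run_fixture(fx2)
  ratio_ref <- fx2$exact$stiffness / fx1$exact$stiffness  # ~8 minus shear
  expect_lte(abs(r2$reaction / r1$reaction - ratio_ref) / ratio_ref, 0.10)
  expect_gt(r2$reaction / r1$reaction, 6)
})

test_that("cantilever reaction converges monotonically from above", {
  reactions <- vapply(c(20, 40, 80), function(nx) {
    run_fixture(cantilever(E = 2.7e3, nu = 0.33, nx = nx, nt = 4))$reaction
  }, 1.0)
  exact <- cantilever(E = 2.7e3, nu = 0.33)$exact$reaction
  expect_true(all(diff(reactions) < 0))       # softening under refinement
  expect_true(all(reactions > 0.95 * exact))  # from above (up to bc effects)
})

test_that("bimaterial bar partitions strain by the series-spring law", {
  # equal moduli: uniform strain
  fx <- bimaterial_series(E1 = 5, E2 = 5, stretch = 1e-3)
  r <- run_fixture(fx)
  expect_equal(r$field$tensors[, "xx"], rep(1e-3, nrow(r$field$tensors)),
               tolerance = 1e-10)
  # 10:1 contrast: the soft block carries 10x the strain, exactly
  fx <- bimaterial_series(E1 = 10, E2 = 1, stretch = 1e-3)
  r <- run_fixture(fx)
  e1 <- mean(r$field$tensors[r$field$region == "block1", "xx"])
  e2 <- mean(r$field$tensors[r$field$region == "block2", "xx"])
  expect_equal(e2 / e1, 10, tolerance = 1e-10)
  expect_lte(r$max_displacement_error, 1e-12)
  # silicon-to-brain contrast (2e5 : 6), partition exact to 1e-8
  fx <- bimaterial_series(E1 = 2e5, E2 = 6, stretch = 1e-3)
  r <- run_fixture(fx)
  e1 <- mean(r$field$tensors[r$field$region == "block1", "xx"])
  e2 <- mean(r$field$tensors[r$field$region == "block2", "xx"])
  expect_equal(e1 / e2, 6 / 2e5, tolerance = 1e-8)
})

test_that("the fixture gate summary passes every check", {
  res <- verify_all()
  expect_true(all(res$pass))
})
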