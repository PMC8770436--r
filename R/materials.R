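#' Isotropic linear-elastic material
#'
#' Bundles an elastic modulus and Poisson ratio with the derived Lame
#' constants. All moduli are in MPa; with lengths in micrometres this keeps
#' the unit system self-consistent (stresses in MPa, strains dimensionless).
#'
#' @param name material name.
#' @param E elastic modulus, MPa. Must be positive.
#' @param nu Poisson ratio, in `[0, 0.5)`. The incompressible limit is not
#'   supported by the displacement formulation.
#' @return an object of class `"material"`: a list with `name`, `E`, `nu`,
#'   `lambda`, `mu`.
#' @export
#' @examples
#' material("brain", E = 6, nu = 0.45)
material <- function(name, E, nu) {
  lm <- lame_parameters(E, nu)
  structure(list(name = name, E = E, nu = nu,
                 lambda = lm[["lambda"]], mu = lm[["mu"]]),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: E = %g MPa, nu = %g (lambda = %g, mu = %g MPa)\n",
              x$name, x$E, x$nu, x$lambda, x$mu))
  invisible(x)
}

#' Lame constants from engineering constants
#'
#' @param E elastic modulus, MPa (> 0).
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return named numeric vector `c(lambda = , mu = )`, MPa.
#' @export
#' @examples
#' lame_parameters(2700, 0.33)
lame_parameters <- function(E, nu) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (E <= 0) stop("elastic modulus must be positive")
  if (nu < 0 || nu >= 0.5)
    stop("Poisson ratio must lie in [0, 0.5); nu = ", nu,
         " (incompressible limit unsupported)")
  c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu     = E / (2 * (1 + nu)))
}

#' Material catalog for the probe--tissue model
#'
#' The probe materials studied (silicon, polyimide, post-insertion PVAc-NC,
#' and a hypothetical probe whose modulus matches the brain) together with
#' the brain-tissue model. PVAc-NC is a polyvinyl acetate
#' cellulose-nanocrystal composite that softens by nearly three orders of
#' magnitude after insertion; only the post-insertion state is simulated
#' (the stiff pre-insertion state is catalogued for reference).
#'
#' The brain modulus default is 6 MPa (6,000 kPa), Poisson ratio 0.45; the
#' hypothetical probe modulus is tied to the configured brain modulus.
#'
#' @param brain_E brain-tissue elastic modulus, MPa. Default 6.
#' @return named list of [material()] objects: `silicon`, `polyimide`,
#'   `pvac_nc`, `pvac_nc_pre`, `hypothetical`, `brain`.
#' @export
#' @examples
#' material_catalog()$silicon
material_catalog <- function(brain_E = 6) {
  list(
    silicon      = material("silicon",      E = 2e5,     nu = 0.278),
    polyimide    = material("polyimide",    E = 2.7e3,   nu = 0.33),
    pvac_nc      = material("pvac_nc",      E = 12.7,    nu = 0.3),
    pvac_nc_pre  = material("pvac_nc_pre",  E = 5.2e3,   nu = 0.38),
    hypothetical = material("hypothetical", E = brain_E, nu = 0.33),
    brain        = material("brain",        E = brain_E, nu = 0.45)
  )
}
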