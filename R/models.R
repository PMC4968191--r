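## Expected-photon models.
##
## Both models work in the flat-Ewald small-angle approximation: at the
## largest in-scope scattering angle (~7.6 deg) Ewald-sphere curvature
## corrections are below 1%.  Expected photons per pixel are
##   n_i = Phi * r_e^2 * dOmega_i * |F(q_i)|^2
## with Phi the incident fluence (photons/um^2), r_e the classical electron
## radius, dOmega_i the pixel solid angle and F the particle form factor in
## electron units.

#' Homogeneous-sphere scattering model
#'
#' A uniform-density sphere described by its diameter and mass density.  The
#' total electron count is derived from the mass density, the sphere volume
#' and an average electrons-per-dalton ratio (0.53 e-/Da, a protein-like
#' average), so the absolute intensity scale is a documented convention
#' rather than a composition-specific value.
#'
#' @slot diameter sphere diameter (nm).
#' @slot massDensity mass density (g/cm^3).
#' @slot electronsPerDalton dimensionless composition ratio.
#' @export
setClass("SphereModel",
  slots = c(diameter = "numeric", massDensity = "numeric",
            electronsPerDalton = "numeric"))

setValidity("SphereModel", function(object) {
  if (object@diameter <= 0) return("diameter must be positive (nm)")
  if (object@massDensity <= 0) return("massDensity must be positive (g/cm^3)")
  if (object@electronsPerDalton <= 0) return("electronsPerDalton must be positive")
  TRUE
})

#' @param diameterNm sphere diameter (nm).
#' @param massDensity mass density (g/cm^3); default 1.381, a packed
#'   virus-particle value.
#' @param electronsPerDalton electrons per dalton of particle mass.
#' @rdname SphereModel-class
#' @export
SphereModel <- function(diameterNm, massDensity = 1.381,
                        electronsPerDalton = 0.53) {
  new("SphereModel", diameter = as.numeric(diameterNm),
      massDensity = as.numeric(massDensity),
      electronsPerDalton = as.numeric(electronsPerDalton))
}

setMethod("show", "SphereModel", function(object) {
  cat(sprintf(
    "SphereModel: d = %.1f nm, rho = %.3f g/cm^3 (%.3g electrons)\n",
    object@diameter, object@massDensity, sphereElectronCount(object)))
})

#' Sphere form factor
#'
#' The normalized homogeneous-sphere form factor
#' \code{f(u) = 3 (sin u - u cos u) / u^3} with \code{u = qR}; \code{f(0)=1}.
#' Evaluated by series expansion near \code{u = 0} for numerical stability.
#'
#' @param u dimensionless \code{qR} values.
#' @return \code{f(u)}, same shape as \code{u}.
#' @export
sphereFormFactor <- function(u) {
  small <- abs(u) < 1e-3
  f <- u
  f[small] <- 1 - u[small]^2 / 10 + u[small]^4 / 280
  ub <- u[!small]
  f[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  f
}

#' Total electron count of a sphere model
#'
#' Electrons from mass density, sphere volume and the electrons-per-dalton
#' ratio.
#'
#' @param model a [SphereModel-class].
#' @return Number of electrons (dimensionless).
#' @export
sphereElectronCount <- function(model) {
  rCm <- model@diameter / 2 * 1e-7
  volCm3 <- 4 / 3 * pi * rCm^3
  massDa <- model@massDensity * volCm3 * .avogadro
  model@electronsPerDalton * massDa
}

#' Expected photon counts from a homogeneous sphere
#'
#' Per-pixel expected photon counts \code{n_i} for a sphere of the given
#' model at incident fluence \code{Phi}:
#' \code{n_i = Phi r_e^2 dOmega_i (N_e f(q_i R))^2}.  At \code{q = 0} the
#' form factor is exactly 1, so the forward pixel sees
#' \code{Phi r_e^2 dOmega N_e^2}.  Linear in fluence.
#'
#' @param model a [SphereModel-class].
#' @param fluence incident fluence, photons per square micrometre, >= 0.
#' @param map a [PixelMap-class].
#' @return Numeric matrix of expected photons per pixel.
#' @export
sphereExpectedPhotons <- function(model, fluence, map) {
  validObject(model)
  stopifnot(is.numeric(fluence), length(fluence) == 1L, fluence >= 0)
  Ne <- sphereElectronCount(model)
  Rang <- model@diameter / 2 * 10          # radius in Angstrom
  f <- sphereFormFactor(map@q * Rang)
  fluence * .re_um^2 * map@solidAngle * (Ne * f)^2
}

#' Icosahedral blob-shell scattering model
#'
#' Twelve identical spherical blobs at the vertices of a regular icosahedron:
#' a minimal orientation-dependent stand-in for a faceted virus capsid,
#' carrying the icosahedral point symmetry without an atomistic density.
#' Scattering is the coherent sum over the blobs on the flat Ewald plane.
#'
#' @slot positions 12 x 3 matrix of unit vertex directions.
#' @slot blobRadius blob radius (nm).
#' @slot circumRadius circumscribed (vertex) radius (nm).
#' @slot nElectrons total electron count of the particle.
#' @slot orientation unit quaternion (w, x, y, z), reference orientation.
#' @export
setClass("IcosaBlobModel",
  slots = c(positions = "matrix", blobRadius = "numeric",
            circumRadius = "numeric", nElectrons = "numeric",
            orientation = "numeric"))

setValidity("IcosaBlobModel", function(object) {
  if (!identical(dim(object@positions), c(12L, 3L)))
    return("positions must be 12 x 3")
  if (object@blobRadius <= 0 || object@circumRadius <= 0)
    return("radii must be positive (nm)")
  if (object@nElectrons <= 0) return("nElectrons must be positive")
  if (abs(sum(object@orientation^2) - 1) > 1e-9)
    return("orientation quaternion must be normalized")
  TRUE
})

#' @param circumRadiusNm vertex (circumscribed) radius of the shell (nm).
#' @param blobRadiusNm radius of each blob (nm).
#' @param nElectrons total electron count (split equally over the blobs).
#' @param orientation unit quaternion; identity by default.
#' @rdname IcosaBlobModel-class
#' @export
IcosaBlobModel <- function(circumRadiusNm = 35.4, blobRadiusNm = 11,
                           nElectrons = 8.2e7,
                           orientation = c(1, 0, 0, 0)) {
  new("IcosaBlobModel", positions = icosahedronVertices(),
      blobRadius = as.numeric(blobRadiusNm),
      circumRadius = as.numeric(circumRadiusNm),
      nElectrons = as.numeric(nElectrons),
      orientation = as.numeric(orientation))
}

setMethod("show", "IcosaBlobModel", function(object) {
  cat(sprintf(
    "IcosaBlobModel: 12 blobs (r = %.1f nm) at circumradius %.1f nm, %.3g e-\n",
    object@blobRadius, object@circumRadius, object@nElectrons))
})

#' Expected photon counts from an oriented icosahedral blob shell
#'
#' Coherent-sum intensity of twelve identical spherical blobs at the rotated
#' icosahedron vertices, flat-Ewald approximation:
#' \code{n_i = Phi r_e^2 dOmega_i |f_blob(q_i)|^2 |sum_j exp(i q_i . r_j)|^2}.
#' Invariant under the icosahedral rotation group of the vertex set.
#'
#' @param model an [IcosaBlobModel-class].
#' @param fluence incident fluence (photons/um^2).
#' @param orientation unit quaternion overriding the model's orientation;
#'   NULL uses the model's.
#' @param map a [PixelMap-class].
#' @return Numeric matrix of expected photons per pixel.
#' @export
icosaExpectedPhotons <- function(model, fluence, orientation = NULL, map) {
  validObject(model)
  if (is.null(orientation)) orientation <- model@orientation
  if (abs(sum(orientation^2) - 1) > 1e-6)
    stop("invalid-orientation: quaternion must be normalized")
  orientation <- orientation / sqrt(sum(orientation^2))
  R <- quatToMat(orientation)
  posAng <- model@positions %*% t(R) * (model@circumRadius * 10)
  geom <- map@geometry
  twoPiLam <- 2 * pi / geom@wavelength
  qx <- twoPiLam * map@xMm / geom@distance
  qy <- twoPiLam * map@yMm / geom@distance
  re <- 0 * qx; im <- re
  for (j in seq_len(12L)) {
    phase <- qx * posAng[j, 1L] + qy * posAng[j, 2L]
    re <- re + cos(phase)
    im <- im + sin(phase)
  }
  fblob <- (model@nElectrons / 12) *
    sphereFormFactor(map@q * model@blobRadius * 10)
  fluence * .re_um^2 * map@solidAngle * fblob^2 * (re^2 + im^2)
}
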