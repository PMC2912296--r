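# Forward model of a liquid aggregate squeezed between non-adhesive parallel
# plates, and the Young-Laplace inversion producing apparent surface tension.
#
# Profile convention: axisymmetric, mirror-symmetric about the equatorial
# plane; the vertical profile between the plates is a circular arc of radius
# R1 through (X, +-H/2) and (R2, 0), where X is the contact-disc radius, R2
# the equatorial radius, and H the plate separation. All lengths in
# micrometres; surface tension in dyn/cm.

# micrometres per centimetre, used wherever sigma (dyn/cm) meets geometry (um)
.UM_PER_CM <- 1e4

#' Side-arc radius of a compressed aggregate profile
#'
#' Radius `R1` of the circular arc that closes the vertical profile of an
#' aggregate compressed between parallel plates: the circle centred on the
#' equatorial plane passing through the plate contact edge `(X, +-H/2)` and
#' the equator `(R2, 0)`.
#'
#' @param R2 Equatorial radius (um).
#' @param X Contact-disc radius (um), `0 < X < R2`.
#' @param H Plate separation (um); a circular-arc profile requires
#'   `H >= 2 * (R2 - X)`.
#' @return Side-arc radius `R1` (um).
#' @examples
#' side_arc_radius(R2 = 2, X = 1, H = 2)  # semicircular bulge: R1 = H/2 = 1
#' @export
side_arc_radius <- function(R2, X, H) {
  d <- R2 - X
  if (any(!is.finite(c(R2, X, H))) || any(X <= 0) || any(H <= 0)) {
    stop("degenerate profile: need X > 0 and H > 0")
  }
  if (any(d <= 0)) {
    stop("degenerate profile: no equatorial bulge (R2 <= X), sigma undefined")
  }
  # tangent pancake profiles sit exactly on H = 2d; tolerate rounding there
  if (any(H < 2 * d * (1 - 1e-9))) {
    stop("no circular-arc solution: H < 2*(R2 - X)")
  }
  pmax((d^2 + H^2 / 4) / (2 * d), H / 2)
}

#' Construct and validate an aggregate profile
#'
#' Bundles the three measured lengths of one compressed-aggregate profile and
#' derives the side-arc radius `R1`. Invariants enforced: `0 < X < R2`,
#' `H > 0`, and arc solvability `H >= 2 * (R2 - X)`.
#'
#' @param X Contact-disc radius (um).
#' @param R2 Equatorial radius (um).
#' @param H Plate separation (um).
#' @return An object of class `"aggregate_profile"`: list with fields
#'   `X`, `R2`, `H`, and derived `R1` (all um).
#' @export
aggregate_profile <- function(X, R2, H) {
  R1 <- side_arc_radius(R2 = R2, X = X, H = H)
  structure(list(X = X, R2 = R2, H = H, R1 = R1),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf(
    "aggregate profile: X = %.4g um, R2 = %.4g um, H = %.4g um (R1 = %.4g um)\n",
    x$X, x$R2, x$H, x$R1))
  invisible(x)
}

.as_profile <- function(profile, X, R2, H) {
  if (!missing(profile) && inherits(profile, "aggregate_profile")) return(profile)
  aggregate_profile(X = X, R2 = R2, H = H)
}

#' Volume of the compressed-aggregate solid of revolution
#'
#' Closed-form volume of the solid obtained by revolving the circular-arc
#' profile `r(z) = c + sqrt(R1^2 - z^2)`, `z` in `[-H/2, H/2]`,
#' `c = R2 - R1`, about the plate axis. For the tangent "pancake" case
#' (`R1 = H/2`, `X = c`) this reduces to
#' `V = 2*pi*a*c^2 + pi^2*a^2*c + (4/3)*pi*a^3` with `a = H/2`.
#'
#' @inheritParams aggregate_profile
#' @param profile Optionally, an `"aggregate_profile"` instead of `X, R2, H`.
#' @return Volume (um^3).
#' @examples
#' profile_volume(X = 1, R2 = 2, H = 2)  # 10*pi/3 + pi^2
#' @export
profile_volume <- function(X, R2, H, profile = NULL) {
  p <- if (!is.null(profile)) profile else aggregate_profile(X, R2, H)
  if (!inherits(p, "aggregate_profile")) stop("invalid profile")
  h <- p$H / 2
  R1 <- p$R1
  cc <- p$R2 - R1
  # R1 >= h always holds for a solvable arc, so both terms are real
  arc <- h * sqrt(max(R1^2 - h^2, 0)) + R1^2 * asin(min(1, h / R1))
  pi * (2 * h * cc^2 + 2 * cc * arc + 2 * h * R1^2 - (2 / 3) * h^3)
}

#' Equivalent uncompressed (spherical) radius
#'
#' @param V Aggregate volume (um^3).
#' @return Radius `R0 = (3V / 4 pi)^(1/3)` (um).
#' @export
uncompressed_radius <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0)) stop("invalid volume: V must be > 0")
  (3 * V / (4 * pi))^(1 / 3)
}

# Laplace geometric denominator D = X^2 * (1/R1 + 1/R2), in um, such that
# F [dyn] = sigma [dyn/cm] * pi * D [um] / .UM_PER_CM
.laplace_denominator <- function(profile) {
  profile$X^2 * (1 / profile$R1 + 1 / profile$R2)
}

#' Apparent surface tension from the Young-Laplace relation
#'
#' Balances the Laplace pressure `F / (pi X^2)` exerted through the contact
#' disc against the mean curvature of the free surface at the equator:
#' `sigma = F / (pi X^2 (1/R1 + 1/R2))`. Lengths are converted from um to cm
#' internally; the result is in dyn/cm.
#'
#' @param F Equilibrium resisting force (dyn), `F >= 0`.
#' @param profile An `"aggregate_profile"` (um lengths).
#' @param step Optional compression step label (1 or 2) carried through.
#' @return List of class `"surface_tension_estimate"` with `sigma` (dyn/cm)
#'   and `step`.
#' @export
compute_surface_tension <- function(F, profile, step = NA_integer_) {
  if (!is.finite(F) || F < 0) stop("invalid force: F must be >= 0")
  if (!inherits(profile, "aggregate_profile")) {
    stop("invalid profile: expected an aggregate_profile")
  }
  sigma <- .UM_PER_CM * F / (pi * .laplace_denominator(profile))
  structure(list(sigma = sigma, step = step),
            class = "surface_tension_estimate")
}

#' Equilibrium shape and force of a liquid aggregate at a given plate gap
#'
#' Forward model: a liquid aggregate of volume `V` and surface tension
#' `sigma`, compressed to gap `H` between non-adhesive plates, takes the
#' tangent pancake shape `R1 = H/2`, `X = c`, `R2 = c + H/2`, where `c` is
#' the positive root of the pancake volume polynomial
#' `2 pi a c^2 + pi^2 a^2 c + (4/3) pi a^3 = V`, `a = H/2`. The equilibrium
#' force follows from the Young-Laplace relation, so
#' [compute_surface_tension()] applied to the output recovers `sigma`
#' exactly.
#'
#' @param sigma Surface tension (dyn/cm), > 0.
#' @param V Aggregate volume (um^3).
#' @param H Plate separation (um); requires `H < 2 * R0`.
#' @return List with `profile` (an `"aggregate_profile"`) and `F` (dyn).
#' @export
solve_equilibrium_shape <- function(sigma, V, H) {
  if (!is.finite(sigma) || sigma <= 0) stop("invalid sigma: must be > 0")
  R0 <- uncompressed_radius(V)
  if (H <= 0 || H >= 2 * R0) {
    stop("plates not touching aggregate: need 0 < H < 2*R0")
  }
  a <- H / 2
  # 2*pi*a*c^2 + pi^2*a^2*c + ((4/3)*pi*a^3 - V) = 0, take the positive root
  A <- 2 * pi * a
  B <- pi^2 * a^2
  C <- (4 / 3) * pi * a^3 - V
  disc <- B^2 - 4 * A * C
  cc <- (-B + sqrt(disc)) / (2 * A)
  if (!is.finite(cc) || cc <= 0) stop("volume infeasible: no positive root")
  profile <- aggregate_profile(X = cc, R2 = cc + a, H = H)
  F <- sigma * pi * .laplace_denominator(profile) / .UM_PER_CM
  list(profile = profile, F = F)
}
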