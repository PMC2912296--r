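# shared fixtures built in code

# per-clone cohort summary values published for the four receptor clones
clone_means <- function() {
  utils::read.csv(system.file("extdata", "clone_cohort_means.csv",
                              package = "tstkit"))
}

# minimal two-aggregate cohort whose sigma and force means equal the given
# values exactly (symmetric spread, so means are preserved)
records_with_means <- function(m1, m2, ratio_F = 1.5, clone = "X",
                               sFn = 30) {
  data.frame(
    aggregate_id = c("a1", "a2"),
    clone = clone, sFn_ug_ml = sFn,
    sigma1 = c(m1 - 0.1, m1 + 0.1),
    sigma2 = c(m2 - 0.05, m2 + 0.05),
    F1 = c(0.9, 1.1),
    F2 = ratio_F * c(1.1, 0.9),
    V_um3 = 4 / 3 * pi * 250^3,
    stringsAsFactors = FALSE)
}

# random valid aggregate profile (um scale); tangent and non-tangent mixes
random_profile <- function() {
  R2 <- stats::runif(1, 150, 400)
  X <- stats::runif(1, 0.15, 0.85) * R2
  d <- R2 - X
  H <- stats::runif(1, 2 * d, min(2 * R2, 6 * d))
  aggregate_profile(X = X, R2 = R2, H = H)
}

# numerical-quadrature volume oracle: revolve r(z) = c + sqrt(R1^2 - z^2)
profile_volume_quadrature <- function(profile) {
  R1 <- profile$R1
  cc <- profile$R2 - R1
  f <- function(z) pi * (cc + sqrt(pmax(R1^2 - z^2, 0)))^2
  stats::integrate(f, -profile$H / 2, profile$H / 2,
                   rel.tol = 1e-12)$value
}
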