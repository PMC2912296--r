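# Seeded generators of synthetic compression measurements: liquid and
# elastic aggregates and mixed cohorts with ground-truth labels. The
# generators exercise the same geometry the analysis inverts, so the
# pipeline is exactly round-trippable at zero noise.

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for synthetic compression measurements
#'
#' Bundles the generator settings. Defaults describe a mid-sized aggregate
#' (uncompressed radius 250 um, i.e. 500 um diameter within the 450-650 um
#' working range) compressed to gaps of 1.6 R0 and 1.2 R0, so the second
#' plate displacement is twice the first, with 2% multiplicative
#' measurement noise on force and geometry.
#'
#' @param seed Integer RNG seed; identical configs give identical outputs.
#' @param noise_F Relative s.d. of multiplicative force noise.
#' @param noise_geom Relative s.d. of multiplicative geometry noise.
#' @param sigma_true True surface tension of liquid aggregates (dyn/cm).
#' @param k_spring Hookean stiffness of elastic aggregates (dyn/um).
#' @param R0 Uncompressed aggregate radius (um).
#' @param H1,H2 Plate gaps (um) of the first and second compression;
#'   requires `H2 < H1 < 2 R0`. Gaps scale with `R0` when volumes are
#'   resampled in [simulate_cohort()].
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, noise_F = 0.02, noise_geom = 0.02,
                       sigma_true = 10, k_spring = 1e-3,
                       R0 = 250, H1 = 400, H2 = 300) {
  if (noise_F < 0 || noise_geom < 0) stop("config error: negative noise")
  if (!(H2 < H1 && H1 < 2 * R0)) stop("config error: need H2 < H1 < 2*R0")
  if (sigma_true <= 0 || k_spring <= 0 || R0 <= 0) {
    stop("config error: sigma_true, k_spring, R0 must be > 0")
  }
  structure(list(seed = as.integer(seed), noise_F = noise_F,
                 noise_geom = noise_geom, sigma_true = sigma_true,
                 k_spring = k_spring, R0 = R0, H1 = H1, H2 = H2),
            class = "sim_config")
}

# Multiplicative measurement noise in a tangency-preserving parametrization:
# X and H get independent log-normal factors; the bulge fraction
# d/(H/2) (= 1 for a tangent pancake) is jittered and clipped at 1, so the
# arc-solvability invariant H >= 2*(R2 - X) holds by construction and no
# rejection (which would bias the apparent tension) is needed.
.noisy_profile_row <- function(profile, F, s_geom, s_F) {
  Xn <- profile$X * exp(stats::rnorm(1, 0, s_geom))
  Hn <- profile$H * exp(stats::rnorm(1, 0, s_geom))
  bulge <- (profile$R2 - profile$X) / (profile$H / 2)
  q <- min(1, bulge * exp(stats::rnorm(1, 0, s_geom)))
  R2n <- Xn + q * Hn / 2
  Fn <- F * exp(stats::rnorm(1, 0, s_F))
  list(F_dyn = Fn, X_um = Xn, R2_um = R2n, H_um = Hn)
}

.compression_row <- function(aggregate_id, step, meas, V, label) {
  data.frame(aggregate_id = aggregate_id, step = step,
             F_dyn = meas$F_dyn, X_um = meas$X_um, R2_um = meas$R2_um,
             H_um = meas$H_um, V_um3 = V, label = label,
             stringsAsFactors = FALSE)
}

#' Simulate two compressions of a viscoelastic-liquid aggregate
#'
#' The aggregate conserves its volume and keeps a constant surface tension
#' `sigma_true` across both compressions; shape and force at each gap come
#' from [solve_equilibrium_shape()]. At zero noise the analysis pipeline
#' recovers `sigma_true` exactly at both steps (elasticity index 0).
#'
#' @param cfg A [sim_config()].
#' @param aggregate_id Identifier attached to both records.
#' @param V Aggregate volume (um^3); defaults to the sphere volume of
#'   `cfg$R0`. Plate gaps scale as `H_i * R0(V) / cfg$R0`.
#' @return Data frame of two compression records (`step` 1 and 2) with
#'   ground-truth `label = "liquid"`.
#' @export
simulate_liquid_aggregate <- function(cfg, aggregate_id = "agg1", V = NULL) {
  if (!inherits(cfg, "sim_config")) stop("config error: not a sim_config")
  if (is.null(V)) V <- 4 / 3 * pi * cfg$R0^3
  scale <- uncompressed_radius(V) / cfg$R0
  .with_seed(cfg$seed, {
    rows <- lapply(c(1, 2), function(step) {
      H <- (if (step == 1) cfg$H1 else cfg$H2) * scale
      eq <- solve_equilibrium_shape(cfg$sigma_true, V, H)
      meas <- .noisy_profile_row(eq$profile, eq$F, cfg$noise_geom, cfg$noise_F)
      .compression_row(aggregate_id, step, meas, V, "liquid")
    })
    do.call(rbind, rows)
  })
}

#' Simulate two compressions of an elastic-solid aggregate
#'
#' Forces follow Hooke's law, `F_i = k_spring * (2 R0 - H_i)`. The recorded
#' profile geometry is chosen so that the Laplace geometric factor
#' `X^2 (1/R1 + 1/R2)` is identical at the two steps (the cells are locked
#' in place and the profile does not spread the way a liquid's does): the
#' apparent surface tension then scales exactly with the applied force, the
#' ideal elastic-solid signature, and the elasticity index is 1 at zero
#' noise.
#'
#' @inheritParams simulate_liquid_aggregate
#' @return Data frame of two compression records with ground-truth
#'   `label = "elastic"`.
#' @export
simulate_elastic_aggregate <- function(cfg, aggregate_id = "agg1", V = NULL) {
  if (!inherits(cfg, "sim_config")) stop("config error: not a sim_config")
  if (is.null(V)) V <- 4 / 3 * pi * cfg$R0^3
  R0 <- uncompressed_radius(V)
  scale <- R0 / cfg$R0
  H <- c(cfg$H1, cfg$H2) * scale
  if (any(2 * R0 - H <= 0)) stop("no contact: H >= 2*R0")
  # equal gaps would give F1 = F2; the analysis rejects that downstream
  Fh <- cfg$k_spring * (2 * R0 - H)
  # step-1 shape: volume-conserving pancake; step-2 contact radius solved so
  # the Laplace denominator matches step 1
  eq1 <- solve_equilibrium_shape(1, V, H[1])  # sigma irrelevant to the shape
  D1 <- .laplace_denominator(eq1$profile)
  a2 <- H[2] / 2
  f <- function(cc) cc^2 * (1 / a2 + 1 / (cc + a2)) - D1
  c2 <- stats::uniroot(f, lower = 1e-9 * R0, upper = 10 * R0,
                       tol = 1e-12 * R0)$root
  prof2 <- aggregate_profile(X = c2, R2 = c2 + a2, H = H[2])
  .with_seed(cfg$seed, {
    m1 <- .noisy_profile_row(eq1$profile, Fh[1], cfg$noise_geom, cfg$noise_F)
    m2 <- .noisy_profile_row(prof2, Fh[2], cfg$noise_geom, cfg$noise_F)
    rbind(.compression_row(aggregate_id, 1, m1, V, "elastic"),
          .compression_row(aggregate_id, 2, m2, V, "elastic"))
  })
}

#' Simulate a mixed cohort of liquid and elastic aggregates
#'
#' Generates `round(n * liquid_fraction)` liquid and the remaining elastic
#' aggregates, with volumes sampled uniformly over a 5-fold range starting
#' at a 450 um diameter sphere, in randomized order. Each aggregate gets its
#' own child seed derived from `cfg$seed`, so the cohort is reproducible and
#' individual aggregates are independent.
#'
#' @param n Number of aggregates (>= 1).
#' @param liquid_fraction Fraction of liquid aggregates in `[0, 1]`.
#' @param cfg A [sim_config()].
#' @return Data frame of `2 n` compression records; the `label` column is
#'   the ground truth ("liquid"/"elastic").
#' @export
simulate_cohort <- function(n, liquid_fraction, cfg = sim_config()) {
  if (n < 1) stop("invalid cohort size")
  if (!is.finite(liquid_fraction) || liquid_fraction < 0 || liquid_fraction > 1) {
    stop("invalid fraction: must be in [0, 1]")
  }
  n_liquid <- floor(n * liquid_fraction + 0.5)
  labels <- c(rep("liquid", n_liquid), rep("elastic", n - n_liquid))
  V_lo <- 4 / 3 * pi * 225^3  # 450 um diameter sphere
  setup <- .with_seed(cfg$seed, {
    list(labels = sample(labels),
         V = stats::runif(n, V_lo, 5 * V_lo))
  })
  rows <- lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed %% 1000003L) * 2048L + i)
    id <- sprintf("agg%03d", i)
    if (setup$labels[i] == "liquid") {
      simulate_liquid_aggregate(cfg_i, aggregate_id = id, V = setup$V[i])
    } else {
      simulate_elastic_aggregate(cfg_i, aggregate_id = id, V = setup$V[i])
    }
  })
  do.call(rbind, rows)
}
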