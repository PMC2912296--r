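# Synthetic aggregate compaction and soluble-fibronectin depletion model.
#
# The model is explicitly invented to emulate the observed dynamics of
# hanging-drop aggregates; it is part of the synthetic-data module only and
# makes no mechanistic claim. Three mass pools (ug/ml of the drop medium):
#
#   Fn  soluble fibronectin
#   M   assembled (insoluble) matrix
#   D   degraded matrix
#
#   dFn/dt = -U + k_off * M            U = k_u * rho * n_cells * Fn/(Km+Fn)
#   dM/dt  =  U - k_off * M - G        G = k_deg * M * 1{Fn < c_crit}
#   dD/dt  =  G
#
# Receptor-mediated uptake U is Michaelis-Menten in Fn and proportional to
# total receptor number (rho * n_cells); matrix turnover k_off*M returns
# material to the soluble pool, giving each clone a steady-state plateau
# (the observed two-timescale depletion); when Fn falls below the critical
# concentration c_crit, assembly can no longer keep up and the matrix
# degrades irreversibly. Fn + M + D = Fn0 at every step (mass balance).
#
# Projected area (relative) tracks the cross-linking matrix, plus a slow
# swelling term once the ligand is depleted:
#   area(t) = 1 - alpha * M/(1+M) + beta * max(0, t - t_dep) * 1{Fn < c_crit}
# The indicator is smoothed over a width `w` inside the integrator so the
# right-hand side stays Lipschitz; t_dep is the first crossing of c_crit.

# relative receptor densities of the four expression clones
.RECEPTOR_LEVELS <- c(L = 1, M = 3, H = 10, HH = 30)

#' Default parameters of the compaction/depletion simulator
#'
#' Values were calibrated once so the model reproduces the qualitative
#' behavior of the hanging-drop assays: monotone compaction at 25,000
#' cells for every receptor level, day-4 decompaction of 50,000-cell
#' high-receptor aggregates after ligand depletion, and a fast-then-flat
#' two-timescale depletion profile whose late rates agree across clones.
#'
#' @param k_u Uptake rate constant (ug/ml per day, per cell and unit
#'   relative receptor density).
#' @param Km Michaelis constant of receptor-mediated uptake (ug/ml).
#' @param k_off Matrix turnover (release) rate (1/day).
#' @param c_crit Critical soluble-Fn concentration below which assembled
#'   matrix degrades (ug/ml).
#' @param k_deg Matrix degradation rate below `c_crit` (1/day).
#' @param alpha Maximum relative area reduction from matrix cross-linking.
#' @param beta Post-depletion swelling rate (relative area per day).
#' @param w Smoothing width of the depletion switch (ug/ml).
#' @param dt RK4 integration step (days).
#' @return Named list of parameters.
#' @export
compaction_params <- function(k_u = 3e-5, Km = 10, k_off = 0.25, c_crit = 2,
                              k_deg = 0.4, alpha = 0.5, beta = 0.03,
                              w = 0.02, dt = 0.01) {
  p <- list(k_u = k_u, Km = Km, k_off = k_off, c_crit = c_crit,
            k_deg = k_deg, alpha = alpha, beta = beta, w = w, dt = dt)
  if (any(vapply(p, function(x) !is.finite(x) || x < 0, logical(1)))) {
    stop("invalid parameter: all compaction parameters must be >= 0")
  }
  if (dt <= 0) stop("invalid parameter: dt must be > 0")
  p
}

# classical RK4 on the three-pool system; returns the dense trajectory
.integrate_pools <- function(g, Fn0, p, t_max) {
  deriv <- function(s) {
    Fn <- s[1]; M <- s[2]
    U <- p$k_u * g * Fn / (p$Km + Fn)
    sw <- 1 / (1 + exp((Fn - p$c_crit) / p$w))
    R <- p$k_off * M
    G <- p$k_deg * M * sw
    c(-U + R, U - R - G, G)
  }
  nt <- max(1L, as.integer(round(t_max / p$dt)))
  out <- matrix(NA_real_, nt + 1L, 4L,
                dimnames = list(NULL, c("t", "Fn", "M", "D")))
  s <- c(Fn0, 0, 0)
  out[1L, ] <- c(0, s)
  dt <- t_max / nt
  for (i in seq_len(nt)) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- c(i * dt, s)
  }
  out
}

#' Simulate an aggregate compaction / ligand depletion time course
#'
#' Runs the invented three-pool depletion model (see the package vignette)
#' from seeding (day 0, all fibronectin soluble) and reports aggregate
#' projected area and soluble-Fn concentration on the requested day grid.
#' Area is normalized to its value at the first reported time point (the
#' day-2 basis for the default grid).
#'
#' @param n_cells Cells per hanging drop (the assays use 25,000 or 50,000).
#' @param rho Relative receptor density: one of `"L"`, `"M"`, `"H"`, `"HH"`
#'   (mapped to 1, 3, 10, 30) or a non-negative number.
#' @param Fn0 Initial soluble fibronectin concentration (ug/ml).
#' @param t_grid Increasing report times (days).
#' @param params Model parameters, see [compaction_params()].
#' @param seed RNG seed; only consumed when `noise_area > 0`.
#' @param noise_area Relative s.d. of multiplicative measurement noise on
#'   the reported areas (0 = deterministic; hand-traced perimeters motivate
#'   values around 0.005).
#' @return Data frame of class `"compaction_series"` with columns `t_day`,
#'   `area_rel`, `Fn_ug_ml`, `M_ug_ml`, `D_ug_ml`; attributes `n_cells`,
#'   `rho`, `Fn0`, `t_dep` (first depletion time, `Inf` if never).
#' @export
simulate_compaction <- function(n_cells = 25000, rho = "M", Fn0 = 30,
                                t_grid = 2:5, params = compaction_params(),
                                seed = 1L, noise_area = 0) {
  if (is.character(rho)) {
    if (!rho %in% names(.RECEPTOR_LEVELS)) {
      stop("invalid parameter: unknown receptor level ", rho)
    }
    rho_num <- .RECEPTOR_LEVELS[[rho]]
  } else {
    rho_num <- rho
  }
  if (!is.finite(rho_num) || rho_num < 0) stop("invalid parameter: rho < 0")
  if (!is.finite(Fn0) || Fn0 < 0) stop("invalid parameter: Fn0 < 0")
  if (n_cells <= 0) stop("invalid parameter: n_cells must be > 0")
  if (length(t_grid) < 1 || any(diff(t_grid) <= 0) || any(t_grid < 0)) {
    stop("invalid parameter: t_grid must be increasing and non-negative")
  }
  traj <- .integrate_pools(rho_num * n_cells, Fn0, params, max(t_grid))
  dep <- traj[, "Fn"] < params$c_crit
  t_dep <- if (any(dep)) {
    i <- which(dep)[1L]
    if (i == 1L) traj[1L, "t"] else {
      # linear interpolation of the crossing time between grid steps
      t0 <- traj[i - 1L, "t"]; t1 <- traj[i, "t"]
      f0 <- traj[i - 1L, "Fn"]; f1 <- traj[i, "Fn"]
      t0 + (f0 - params$c_crit) / (f0 - f1) * (t1 - t0)
    }
  } else Inf
  area_dense <- 1 - params$alpha * traj[, "M"] / (1 + traj[, "M"]) +
    params$beta * pmax(0, traj[, "t"] - t_dep) * (traj[, "t"] >= t_dep)
  pick <- vapply(t_grid, function(tq) which.min(abs(traj[, "t"] - tq)),
                 integer(1))
  area <- area_dense[pick]
  if (noise_area > 0) {
    area <- .with_seed(seed, area * exp(stats::rnorm(length(area), 0,
                                                     noise_area)))
  }
  out <- data.frame(t_day = t_grid,
                    area_rel = area / area[1L],
                    Fn_ug_ml = traj[pick, "Fn"],
                    M_ug_ml = traj[pick, "M"],
                    D_ug_ml = traj[pick, "D"])
  structure(out, class = c("compaction_series", "data.frame"),
            n_cells = n_cells, rho = rho_num, Fn0 = Fn0, t_dep = t_dep)
}
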