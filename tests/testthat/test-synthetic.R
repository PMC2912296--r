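# synthetic compression generators and the compaction/depletion simulator

test_that("generators are deterministic in their config", {
  cfg <- sim_config(seed = 11)
  expect_identical(simulate_liquid_aggregate(cfg), simulate_liquid_aggregate(cfg))
  expect_identical(simulate_elastic_aggregate(cfg), simulate_elastic_aggregate(cfg))
  expect_identical(simulate_cohort(8, 0.5, cfg), simulate_cohort(8, 0.5, cfg))
  s1 <- simulate_compaction(50000, "HH", seed = 2, noise_area = 0.005)
  s2 <- simulate_compaction(50000, "HH", seed = 2, noise_area = 0.005)
  expect_identical(s1, s2)
  f1 <- generate_fiber_image(10, img_size = 96, seed = 9)
  f2 <- generate_fiber_image(10, img_size = 96, seed = 9)
  expect_identical(f1$image, f2$image)
})

test_that("noise-free liquid aggregates invert to sigma_true with E = 0", {
  cfg <- sim_config(seed = 5, noise_F = 0, noise_geom = 0, sigma_true = 10)
  rec <- analyze_compressions(simulate_liquid_aggregate(cfg))
  expect_equal(rec$sigma1, 10, tolerance = 1e-9)
  expect_equal(rec$sigma2, 10, tolerance = 1e-9)
  expect_equal(rec$E, 0, tolerance = 1e-9)
  expect_equal(rec$verdict, "liquid")
})

test_that("noise-free elastic aggregates are ideal Hookean with E = 1", {
  cfg <- sim_config(seed = 5, noise_F = 0, noise_geom = 0)
  raw <- simulate_elastic_aggregate(cfg)
  # Hooke's law: doubled plate displacement doubles the force
  d <- 2 * cfg$R0 - c(cfg$H1, cfg$H2)
  expect_equal(raw$F_dyn[2] / raw$F_dyn[1], d[2] / d[1], tolerance = 1e-12)
  rec <- analyze_compressions(raw)
  expect_equal(rec$E, 1, tolerance = 1e-9)
  expect_equal(rec$verdict, "elastic")
  # apparent tension scales with the force (sigma2/sigma1 = F2/F1)
  expect_equal(rec$sigma2 / rec$sigma1, rec$F2 / rec$F1, tolerance = 1e-9)
})

test_that("cohort generator hits the requested liquid fraction exactly", {
  cfg <- sim_config(seed = 21, noise_F = 0, noise_geom = 0)
  coh <- simulate_cohort(20, 0.6, cfg)
  expect_equal(nrow(coh), 40)
  labels <- coh$label[coh$step == 1]
  expect_equal(sum(labels == "liquid"), 12)
  expect_equal(sum(labels == "elastic"), 8)
  rec <- analyze_compressions(coh)
  expect_equal(rec$verdict, rec$label)  # perfect recovery at zero noise
  coh19 <- simulate_cohort(20, 0.95, cfg)
  expect_equal(sum(coh19$label[coh19$step == 1] == "liquid"), 19)
  expect_error(simulate_cohort(20, 1.2, cfg), "invalid fraction")
})

test_that("classification stays accurate under 2% measurement noise", {
  acc <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, noise_F = 0.02, noise_geom = 0.02)
    rec <- analyze_compressions(simulate_cohort(20, 0.6, cfg))
    mean(rec$verdict == rec$label)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("compaction model conserves fibronectin mass", {
  for (nc in c(25000, 50000)) {
    s <- simulate_compaction(nc, "HH", Fn0 = 30, t_grid = seq(1, 5, 0.5))
    expect_equal(s$Fn_ug_ml + s$M_ug_ml + s$D_ug_ml, rep(30, nrow(s)),
                 tolerance = 1e-8)
  }
})

test_that("compaction dynamics reproduce the observed qualitative regimes", {
  # no receptor: nothing is consumed, area flat
  s0 <- simulate_compaction(25000, 0, t_grid = 2:5)
  expect_equal(s0$Fn_ug_ml, rep(30, 4), tolerance = 1e-10)
  expect_equal(s0$area_rel, rep(1, 4), tolerance = 1e-10)
  # 25,000 cells: monotone non-increasing area for every clone
  for (rho in c("L", "M", "H", "HH")) {
    s <- simulate_compaction(25000, rho, t_grid = 2:5)
    expect_true(all(diff(s$area_rel) <= 1e-10), label = paste("clone", rho))
    expect_gt(min(s$Fn_ug_ml), compaction_params()$c_crit)
  }
  # 50,000 cells, highest expressor: ligand depletes and the aggregate
  # decompacts on day 4
  s50 <- simulate_compaction(50000, "HH", t_grid = 2:5)
  expect_lt(attr(s50, "t_dep"), 4)
  expect_gt(s50$area_rel[s50$t_day == 4], s50$area_rel[s50$t_day == 3])
})

test_that("soluble-Fn trajectories are ordered in receptor density", {
  t_grid <- seq(0.5, 5, 0.5)
  Fn <- sapply(c(1, 3, 10, 30), function(r)
    simulate_compaction(25000, r, t_grid = t_grid)$Fn_ug_ml)
  expect_true(all(apply(Fn, 1, function(x) all(diff(x) <= 1e-9))))
})

test_that("RK4 trajectories are stable under step halving", {
  p1 <- compaction_params(dt = 0.01)
  p2 <- compaction_params(dt = 0.005)
  g <- expand.grid(nc = c(25000, 50000), rho = c("M", "HH"),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    a <- simulate_compaction(g$nc[i], g$rho[i], t_grid = 2:5, params = p1)
    b <- simulate_compaction(g$nc[i], g$rho[i], t_grid = 2:5, params = p2)
    expect_equal(a$Fn_ug_ml, b$Fn_ug_ml, tolerance = 1e-4)
    expect_equal(a$area_rel, b$area_rel, tolerance = 1e-4)
  }
})

test_that("fiber image generator: blank, calibration and placement", {
  blank <- generate_fiber_image(0, img_size = 64, background = 10, seed = 1)
  expect_equal(fiber_density(blank$image), 10)
  expect_length(blank$lengths_um, 0)
  fb <- generate_fiber_image(12, img_size = 160, seed = 3)
  expect_length(fb$lengths_um, 12)
  expect_true(all(fb$image >= 0 & fb$image <= 255))
  expect_true(is.integer(fb$image))
  # overcrowded request cannot be placed without overlap
  expect_error(
    generate_fiber_image(500, img_size = 64, length_mean = 20,
                         max_attempts = 5, seed = 1),
    "placement failure")
})
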