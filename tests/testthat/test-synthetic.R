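study_spec <- function(sigma = 0, n_experts = 1, snap = FALSE,
                       jitter = 0) {
  mats <- fixture_matrices()
  panel_spec(
    weights = lapply(mats, function(m) unname(compute_weights(m))),
    intensities = fixture_intensities(),
    n_experts = n_experts, sigma = sigma, snap = snap,
    intensity_jitter = jitter)
}

test_that("generated consistent matrices have ratio entries and CI = 0", {
  m <- generate_consistent_matrix(c(0.5, 0.25, 0.25))
  expect_equal(m[1, 2], 2)
  expect_equal(m[2, 3], 1)
  set.seed(31)
  for (rep in 1:10) {
    w <- random_weights(sample(2:9, 1))
    m <- generate_consistent_matrix(w)
    expect_length(validate_matrix(m), 0)
    expect_equal(consistency(m)$ci, 0, tolerance = 1e-12)
    expect_equal(unname(compute_weights(m)), w, tolerance = 1e-9)
  }
  expect_error(generate_consistent_matrix(c(0.5, -0.1)),
               class = "swotahp_spec")
})

test_that("perturbation is seed-deterministic and identity at sigma 0", {
  m <- generate_consistent_matrix(c(0.6, 0.3, 0.1))
  expect_equal(unclass(perturb_matrix(m, 0)), unclass(m))
  p1 <- perturb_matrix(m, 0.3, seed = 99)
  p2 <- perturb_matrix(m, 0.3, seed = 99)
  expect_identical(unclass(p1), unclass(p2))
  p3 <- perturb_matrix(m, 0.3, seed = 100)
  expect_false(identical(unclass(p1), unclass(p3)))
  expect_length(validate_matrix(p1), 0)  # still reciprocal
  expect_error(perturb_matrix(m, -1), class = "swotahp_spec")
})

test_that("snapped perturbations land on the Saaty grid, ties toward 1", {
  m <- generate_consistent_matrix(random_weights(5))
  p <- perturb_matrix(m, 0.5, snap = TRUE, seed = 41)
  grid <- saaty_scale()
  expect_true(all(vapply(as.vector(unclass(p)),
                         function(x) any(abs(x - grid) < 1e-12), TRUE)))
  # midpoint between 1 and 2 in log space snaps to the milder judgment 1
  expect_equal(snap_to_saaty(sqrt(2)), 1)
  expect_equal(snap_to_saaty(c(3.2, 0.3)), c(3, 1/3))
})

test_that("CR pass rate decreases monotonically with judgment noise", {
  m <- generate_consistent_matrix(c(0.4, 0.3, 0.2, 0.1))
  pass_rate <- function(sigma) {
    mean(vapply(1:100, function(s) {
      consistency(perturb_matrix(m, sigma, seed = s))$consistent
    }, TRUE))
  }
  rates <- vapply(c(0.05, 0.4, 0.8), pass_rate, 0)
  expect_gt(rates[1], 0.95)
  expect_lt(rates[3], rates[1])
  expect_true(all(diff(rates) <= 0))
})

test_that("synthetic panels validate and respect the intensity jitter", {
  spec <- study_spec(sigma = 0.2, n_experts = 5, jitter = 1)
  panel <- generate_panel(spec, seed = 17)
  expect_s3_class(panel, "expert_panel")
  expect_length(panel$judgments$S, 5)
  for (g in names(panel$intensities)) {
    sc <- panel$intensities[[g]]
    lat <- spec$intensities[[g]]
    expect_true(all(abs(abs(sc) - rep(abs(lat), each = 5)) <= 1))
    expect_true(all(abs(sc) >= 1 & abs(sc) <= 9))
    expect_true(all(sign(sc) == rep(sign(lat), each = 5)))
  }
  # determinism of the whole panel
  p2 <- generate_panel(spec, seed = 17)
  expect_identical(lapply(panel$judgments$S, unclass),
                   lapply(p2$judgments$S, unclass))
})

test_that("the noise-free synthetic pipeline equals the analytic one", {
  sim <- simulate_strategy_distribution(study_spec(sigma = 0),
                                        replicates = 5, seed = 2)
  st <- fixture_strategy()
  expect_equal(sim$n_rejected, 0)
  expect_equal(sim$theta, rep(st$theta_deg, 5), tolerance = 1e-9)
  expect_equal(sim$rho, rep(st$rho, 5), tolerance = 1e-9)
  expect_equal(names(sim$zone_counts), st$zone$label)
})

test_that("balanced positive and negative intensities pin rho at one half", {
  # S'*O' = W'*T' (2*1 = 1*2) without the centroid degenerating
  spec <- panel_spec(
    weights = list(S = c(0.6, 0.4), W = c(0.6, 0.4),
                   O = c(0.7, 0.3), T = c(0.7, 0.3)),
    intensities = list(S = c(2, 2), W = c(-1, -1),
                       O = c(1, 1), T = c(-2, -2)),
    n_experts = 1, sigma = 0)
  sim <- simulate_strategy_distribution(spec, replicates = 3, seed = 4)
  expect_equal(sim$rho, rep(0.5, 3), tolerance = 1e-12)
  # exactly mirror-symmetric totals degenerate to the origin instead
  expect_error(build_strategy(c(S = 2, W = -2, O = 1, T = -1)),
               class = "swotahp_degenerate")
})

test_that("azimuth dispersion grows with noise around the noise-free value", {
  st <- fixture_strategy()
  sims <- lapply(c(0.1, 0.5), function(sg) {
    simulate_strategy_distribution(study_spec(sigma = sg, n_experts = 3),
                                   replicates = 40, seed = 8)
  })
  sd_small <- stats::sd(sims[[1]]$theta)
  sd_large <- stats::sd(sims[[2]]$theta)
  expect_lt(abs(mean(sims[[1]]$theta) - st$theta_deg), 5)
  expect_lt(sd_small, sd_large)
})

test_that("an all-rejected simulation raises an explicit error", {
  m <- comparison_matrix(rbind(c(1, 9, 1/9), c(1/9, 1, 9), c(9, 1/9, 1)))
  spec <- study_spec()
  sim_err <- simulate_strategy_distribution
  # force rejection via an impossibly strict CR threshold
  expect_error(sim_err(spec, replicates = 3, seed = 1, cr_threshold = 0),
               class = "swotahp_all_rejected")
})

test_that("panel specs round-trip through YAML", {
  spec <- study_spec(sigma = 0.25, n_experts = 4, snap = TRUE, jitter = 1)
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(yaml::as.yaml(list(
    groups = lapply(names(spec$weights), function(g) list(
      weights = spec$weights[[g]],
      intensities = spec$intensities[[g]])) |>
      stats::setNames(names(spec$weights)),
    n_experts = spec$n_experts, sigma = spec$sigma, snap = spec$snap,
    intensity_jitter = spec$intensity_jitter)), path)
  spec2 <- read_panel_spec(path)
  # yaml prints numerics at ~8 significant digits
  expect_equal(spec2$weights, spec$weights, tolerance = 1e-6)
  expect_equal(spec2$sigma, 0.25)
  expect_true(spec2$snap)
})
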