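# Frozen expected values below were verified by recomputing the published
# worked example's tables before being asserted.

test_that("sum-product weights reproduce the worked example", {
  mats <- fixture_matrices()
  expect_equal(unname(compute_weights(mats$S)),
               c(0.0672, 0.0942, 0.2429, 0.5956), tolerance = 5e-4)
  expect_equal(unname(compute_weights(mats$W)),
               c(0.0978, 0.7151, 0.1871), tolerance = 5e-4)
  expect_equal(unname(compute_weights(mats$O)),
               c(0.2840, 0.1715, 0.4708, 0.0736), tolerance = 5e-4)
  expect_equal(unname(compute_weights(mats$T)),
               c(0.2298, 0.1221, 0.6479), tolerance = 5e-4)
})

test_that("equal-importance and consistent matrices give exact weights", {
  for (n in c(3, 5, 9)) {
    m <- comparison_matrix(matrix(1, n, n))
    expect_equal(unname(compute_weights(m)), rep(1 / n, n))
  }
  # for a consistent matrix every normalised column equals w exactly
  w <- c(0.6, 0.3, 0.1)
  m <- generate_consistent_matrix(w)
  expect_equal(unname(compute_weights(m)), w, tolerance = 1e-12)
})

test_that("AW multiplies the original (not normalised) matrix by weights", {
  mats <- fixture_matrices()
  w <- compute_weights(mats$W)
  expect_equal(unname(compute_aw(mats$W, w)),
               c(0.2935, 2.1483, 0.5615), tolerance = 5e-4)
  # all-ones: AW = 1 for uniform weights
  m <- comparison_matrix(matrix(1, 3, 3))
  expect_equal(unname(compute_aw(m, rep(1 / 3, 3))), rep(1, 3))
  # consistent matrix: AW = n * w (algebraic identity)
  w <- random_weights(4)
  m <- generate_consistent_matrix(w)
  expect_equal(unname(compute_aw(m, compute_weights(m))), 4 * w / sum(w),
               tolerance = 1e-12)
  expect_error(compute_aw(mats$W, 1:4), class = "swotahp_dim_mismatch")
})

test_that("consistency diagnostics reproduce the worked example", {
  mats <- fixture_matrices()
  res <- lapply(mats, consistency)
  expect_equal(res$W$lambda_max, 3.00198, tolerance = 2e-3)
  expect_equal(res$S$lambda_max, 4.2301, tolerance = 2e-3)
  expect_equal(res$O$lambda_max, 4.05136, tolerance = 2e-3)
  expect_equal(res$T$lambda_max, 3.00369, tolerance = 2e-3)
  expect_equal(res$S$ci, 0.0766, tolerance = 2e-3)
  expect_equal(res$W$ci, 0.0009, tolerance = 2e-3)
  for (r in res) {
    expect_true(r$consistent)
    expect_lt(r$cr, 0.1)
    expect_equal(r$cr, r$ci / r$ri)
  }
})

test_that("a consistent 3x3 with transitive judgments has CI exactly 0", {
  # oracle: eigen() on the matrix confirms lambda_max = 3
  m <- rbind(c(1, 2, 6), c(1/2, 1, 3), c(1/6, 1/3, 1))
  ev <- eigen(m)$values
  expect_equal(max(Re(ev)), 3, tolerance = 1e-12)
  r <- consistency(comparison_matrix(m))
  expect_equal(r$lambda_max, 3, tolerance = 1e-12)
  expect_equal(r$ci, 0, tolerance = 1e-12)
  expect_equal(r$cr, 0, tolerance = 1e-12)
})

test_that("n = 2 and n = 1 are consistent by definition with CR = 0", {
  r <- consistency(comparison_matrix(rbind(c(1, 5), c(1/5, 1))))
  expect_equal(r$cr, 0)
  expect_true(r$consistent)
  expect_equal(r$ri, 0)
  r1 <- consistency(matrix(1, 1, 1))
  expect_equal(r1$weights, 1)
  expect_true(r1$consistent)
  expect_error(consistency(comparison_matrix(matrix(1, 10, 10),
                                             validate = FALSE)),
               class = "swotahp_order")
})

test_that("CR exactly at the threshold fails the test", {
  m <- fixture_matrices()$S
  r <- consistency(m, cr_threshold = consistency(m)$cr)
  expect_false(r$consistent)
})

test_that("the RI table override changes CR but not the weights", {
  m <- fixture_matrices()$S
  classic <- c("1" = 0, "2" = 0, "3" = 0.58, "4" = 0.90, "5" = 1.12,
               "6" = 1.24, "7" = 1.32, "8" = 1.41, "9" = 1.45)
  r1 <- consistency(m)
  r2 <- consistency(m, ri_table = classic)
  expect_equal(r1$weights, r2$weights)
  expect_equal(r2$ri, 0.90)
  expect_equal(r2$cr, r2$ci / 0.90)
})

test_that("weights always normalise and lambda_max >= n, = n iff consistent", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    m <- random_saaty_matrix(n)
    w <- compute_weights(m)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
    r <- consistency(m)
    expect_gte(r$lambda_max, n - 1e-9)
  }
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    m <- generate_consistent_matrix(random_weights(n))
    expect_equal(consistency(m)$lambda_max, n, tolerance = 1e-9)
    pm <- perturb_matrix(m, sigma = 0.4, seed = rep)
    if (max(abs(unclass(pm) - unclass(m))) > 1e-6) {
      expect_gt(consistency(pm)$lambda_max, n)
    }
  }
})

test_that("consistent-matrix weights are recovered exactly", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    w <- random_weights(n)
    m <- generate_consistent_matrix(w)
    expect_equal(unname(compute_weights(m)), w, tolerance = 1e-9)
  }
})

test_that("sum-product weights track the principal eigenvector when CR < 0.1", {
  # eigen() is the independent oracle; the two methods differ by design,
  # so this is a sanity band, not an identity
  set.seed(11)
  checked <- 0
  while (checked < 15) {
    n <- sample(3:5, 1)
    m <- random_saaty_matrix(n)
    r <- consistency(m)
    if (!r$consistent) next
    checked <- checked + 1
    ev <- eigen(unclass(m))
    pe <- Re(ev$vectors[, which.max(Re(ev$values))])
    pe <- pe / sum(pe)
    expect_true(all(abs(unname(r$weights) - pe) < 0.05))
  }
})

test_that("permuting factors permutes weights identically", {
  set.seed(3)
  m <- fixture_matrices()$O
  w <- compute_weights(m)
  p <- sample(4)
  mp <- comparison_matrix(unclass(m)[p, p],
                          factor_ids = attr(m, "factor_ids")[p])
  expect_equal(unname(compute_weights(mp)), unname(w)[p], tolerance = 1e-12)
})

test_that("AHP results serialise to JSON with the documented fields", {
  j <- jsonlite::fromJSON(ahp_result_json(consistency(fixture_matrices()$W)))
  expect_named(j, c("group_id", "factor_ids", "weights", "aw", "lambda_max",
                    "ci", "ri", "cr", "consistent"))
  expect_true(j$consistent)
  expect_equal(j$weights[2], 0.7151, tolerance = 5e-4)
})
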