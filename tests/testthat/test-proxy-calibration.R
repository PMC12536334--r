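test_that("effect-unit calibration recovers exact affine relationships", {
  eu_psd <- seq(-5, -2, length.out = 10)
  fit <- eu_calibration(eu_psd, eu_psd)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$mean_error, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_true(fit$ci95[1] <= fit$mean_error && fit$mean_error <= fit$ci95[2])

  # affine equivariance: shifting x by c moves the intercept by -slope*c
  fit2 <- eu_calibration(eu_psd + 0.7, eu_psd)
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept - fit$slope * 0.7)
  expect_equal(fit2$r2, fit$r2)

  expect_error(eu_calibration(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(eu_calibration(1:2, 1:2), "3 pairs")

  g <- glance(fit)
  expect_equal(g$r_squared, 1)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], 1)
})

test_that("in-sample mean error of an intercept OLS fit is numerically zero", {
  set.seed(21)
  x <- stats::rnorm(30)
  y <- 0.8 * x + stats::rnorm(30, sd = 0.3)
  fit <- eu_calibration(x, y)
  expect_lt(abs(fit$mean_error), 1e-14)
  expect_gt(fit$error_sd, 0)
})

test_that("k-fold partition covers all points in balanced folds, reproducibly", {
  set.seed(99)
  for (i in 1:15) {
    n <- sample(5:60, 1)
    k <- sample(2:min(8, n), 1)
    pairs <- tibble::tibble(eu_psd = stats::rnorm(n),
                            eu_biota = stats::rnorm(n))
    cv <- kfold_validate(pairs, k = k, seed = i)
    expect_equal(length(cv$folds), n)
    expect_setequal(unique(cv$folds), seq_len(k))
    sizes <- tabulate(cv$folds, k)
    expect_lte(max(sizes) - min(sizes), 1) # balanced
    expect_equal(sum(cv$per_fold$n), n) # every point held out once
  }
  pairs <- tibble::tibble(eu_psd = stats::rnorm(20), eu_biota = stats::rnorm(20))
  expect_identical(glance(kfold_validate(pairs, seed = 4)),
                   glance(kfold_validate(pairs, seed = 4)))
  expect_error(kfold_validate(pairs[1:3, ], k = 5), "at least k")
})

test_that("cross-validation of noiseless linear data has zero error everywhere", {
  pairs <- tibble::tibble(eu_psd = seq(-4, -1, length.out = 20))
  pairs$eu_biota <- 1.3 * pairs$eu_psd + 0.4
  pairs$pc_crit <- 1e-4
  pairs$bcf <- 100
  cv <- kfold_validate(pairs, k = 5, seed = 2)
  expect_equal(cv$per_fold$mean_error_eu, rep(0, 5), tolerance = 1e-10)
  expect_equal(cv$mean_error, 0, tolerance = 1e-10)
  expect_equal(cv$mean_error_ng_g, 0, tolerance = 1e-8)
})

test_that("CV mean error matches the in-sample residual mean on large n", {
  set.seed(123)
  n <- 1000
  x <- stats::rnorm(n)
  y <- 0.9 * x + stats::rnorm(n, sd = 0.5)
  pairs <- tibble::tibble(eu_psd = x, eu_biota = y)
  cv <- kfold_validate(pairs, k = 5, seed = 7)
  fit <- eu_calibration(x, y)
  # both estimate the same (zero-mean) error distribution
  expect_lt(abs(cv$mean_error - fit$mean_error), 0.05)
})

test_that("fitted slope approaches truth as proxy noise vanishes", {
  true_slope <- 1.0
  slope_err <- vapply(c(0.5, 0.1, 0), function(noise) {
    errs <- vapply(1:200, function(s) {
      set.seed(s)
      x <- stats::runif(30, -5, -2)
      y <- true_slope * x - 2.5 + stats::rnorm(30, sd = noise)
      eu_calibration(x, y)$slope - true_slope
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_true(all(diff(slope_err) <= 1e-12))
  expect_equal(slope_err[3], 0, tolerance = 1e-12)
})

test_that("effect unit and back-calculated concentration are exact inverses", {
  set.seed(8)
  for (i in 1:50) {
    c0 <- stats::runif(1, 0.01, 500)
    pc <- 10^stats::runif(1, -6, -3)
    bcf <- stats::runif(1, 5, 5000)
    eu <- effect_unit(c0, pc, bcf)
    expect_equal(predict_internal_concentration(eu, pc, bcf), c0)
  }
  expect_equal(predict_internal_concentration(-3, 1e-1, 10), 1) # denom 1000 ng/g
  expect_equal(predict_internal_concentration(0, 1e-1, 10), 1000)
})

test_that("toxic-unit crosscheck flags routes that misclassify the threshold", {
  # constructed so tissue exceeds -3 but water does not
  routes <- tu_crosscheck(
    disk_mass_ng = c(anion = 1.75, cation = 1.75),
    c_water_ng_L = 5, c_tissue_ng_g = 5,
    ec50_ug_L = 20.9, bcf_L_kg = 9.5,
    rs_L_day = c(anion = 0.05, cation = 0.05)
  )
  tissue <- routes[routes$route == "tissue", ]
  water <- routes[routes$route == "water", ]
  expect_true(tissue$exceeds)
  expect_false(water$exceeds)
  expect_false(water$agrees_with_tissue)
  expect_true(all(routes$agrees_with_tissue[routes$route == "psd_measured"]))
  expect_true(all(routes$agrees_with_tissue[routes$route == "psd_theoretical"]))

  # identical internal concentrations give identical TU on tissue/sampler routes
  same <- tu_crosscheck(
    disk_mass_ng = c(hlb = 63 * 0.0115),
    c_tissue_ng_g = 63, ec50_ug_L = 2, bcf_L_kg = 100
  )
  expect_equal(same$log_tu[same$route == "psd_measured"],
               same$log_tu[same$route == "tissue"])
  expect_true("water" %in% attr(same, "omitted"))

  # scaling all concentrations x10 adds exactly 1 to every route
  r1 <- tu_crosscheck(disk_mass_ng = c(anion = 1.75), c_water_ng_L = 5,
                      c_tissue_ng_g = 5, ec50_ug_L = 20.9, bcf_L_kg = 9.5,
                      rs_L_day = c(anion = 0.05))
  r10 <- tu_crosscheck(disk_mass_ng = c(anion = 17.5), c_water_ng_L = 50,
                       c_tissue_ng_g = 50, ec50_ug_L = 20.9, bcf_L_kg = 9.5,
                       rs_L_day = c(anion = 0.05))
  expect_equal(r10$log_tu, r1$log_tu + 1)
})
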