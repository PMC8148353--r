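test_that("observer_model validates its parameters", {
  expect_error(observer_model(radial_jitter_sd = -1), "sd")
  expect_error(observer_model(misalignment_prob = 1.5), "prob")
  expect_error(observer_model(misalignment_arc = 360), "arc")
  expect_error(observer_model(smoothing_window = 4), "odd")
  o <- observer_model(sector_bias = list(c(60, 120, 5)))
  expect_equal(o$sector_bias$offset, 5)
})

test_that("an unperturbed true disc rasterizes exactly as its ellipse", {
  cfg <- tiny_config(n = 1, seed = 8)
  set.seed(8)
  disc <- generate_true_disc("normal", c(486, 724), cfg)
  expect_identical(disc$mask, ellipse_to_mask(disc$params, c(486, 724)))
  expect_null(disc$pert)
  # determinism: same RNG state, same output
  set.seed(8)
  disc2 <- generate_true_disc("normal", c(486, 724), cfg)
  expect_identical(disc2$mask, disc$mask)
  expect_equal(unclass(disc2$params), unclass(disc$params))
})

test_that("a perturbed disc deviates from every ellipse but stays near one", {
  cfg <- tiny_config(n = 1, seed = 21, perturbation = 0.15)
  set.seed(21)
  disc <- generate_true_disc("normal", c(486, 724), cfg)
  base <- ellipse_to_mask(disc$params, c(486, 724))
  d_base <- dice_coefficient(disc$mask, base)
  expect_lt(d_base, 1)
  expect_gt(d_base, 0.8)
  # polar-form area oracle: sum over pixels of the analytic radius rule
  best <- refit_tracing(disc$mask, c(486, 724))
  expect_lt(dice_coefficient(disc$mask, best), 1)
})

test_that("a zero-noise observer reproduces the true disc", {
  cfg <- tiny_config(n = 1, seed = 13)
  rec <- generate_study(cfg)[[1]]
  truth <- rec$tracings$ground_truth
  for (r in c("od1", "od2")) {
    m <- polyline_to_mask(rec$tracings[[r]], rec$shape)
    expect_gte(dice_coefficient(m, truth), 0.99)
    expect_gte(region_kappa(m, truth)$kappa, 0.98)
    expect_lte(average_boundary_distance(truth, m)$mu_d, 0.5)
  }
})

test_that("a forced misalignment displaces exactly one arc of the stated width", {
  cfg <- tiny_config(n = 1, seed = 77)
  set.seed(77)
  disc <- generate_true_disc("normal", c(486, 724), cfg)
  o <- observer_model(radial_jitter_sd = 0, misalignment_prob = 1,
                      misalignment_arc = 60, misalignment_offset = 8,
                      smoothing_window = 1)
  tr <- simulate_tracing(disc$mask, disc$params, o)
  ctr <- c(disc$params$cx, disc$params$cy)
  r_obs <- sqrt((tr$points[, 1] - ctr[1])^2 + (tr$points[, 2] - ctr[2])^2)
  r_true <- radial_distance(disc$mask, ctr, 0:359)
  delta <- r_obs - r_true
  expect_equal(sum(abs(delta - 8) < 1e-9), 60)   # one 60-degree arc at +8
  expect_equal(sum(abs(delta) < 1e-9), 300)      # everything else untouched
  # the displaced angles are contiguous on the circle
  idx <- which(abs(delta - 8) < 1e-9) - 1
  gaps <- diff(sort(idx))
  expect_lte(sum(gaps > 1), 1)  # at most one wrap-around gap
})

test_that("radial jitter has the stated zero-mean Gaussian magnitude", {
  cfg <- tiny_config(n = 1, seed = 55)
  set.seed(55)
  disc <- generate_true_disc("normal", c(486, 724), cfg)
  o <- observer_model(radial_jitter_sd = 2, misalignment_prob = 0,
                      smoothing_window = 1)
  ctr <- c(disc$params$cx, disc$params$cy)
  r_true <- radial_distance(disc$mask, ctr, 0:359)
  set.seed(56)
  errs <- replicate(100, {
    tr <- simulate_tracing(disc$mask, disc$params, o)
    sqrt((tr$points[, 1] - ctr[1])^2 + (tr$points[, 2] - ctr[2])^2) - r_true
  })
  expect_lt(abs(mean(errs)), 0.3)
  expect_gt(sd(as.vector(errs)), 1.6)
  expect_lt(sd(as.vector(errs)), 2.4)
})

test_that("circular smoothing reduces jitter without biasing the radius", {
  cfg <- tiny_config(n = 1, seed = 60)
  set.seed(60)
  disc <- generate_true_disc("normal", c(486, 724), cfg)
  ctr <- c(disc$params$cx, disc$params$cy)
  r_true <- radial_distance(disc$mask, ctr, 0:359)
  mk <- function(w) observer_model(radial_jitter_sd = 2,
                                   misalignment_prob = 0,
                                   smoothing_window = w)
  set.seed(61); rough <- simulate_tracing(disc$mask, disc$params, mk(1))
  set.seed(61); smooth <- simulate_tracing(disc$mask, disc$params, mk(5))
  dev <- function(tr) sqrt((tr$points[, 1] - ctr[1])^2 +
                           (tr$points[, 2] - ctr[2])^2) - r_true
  expect_lt(sd(dev(smooth)), sd(dev(rough)))
  expect_lt(abs(mean(dev(smooth))), 0.5)
})

test_that("study generation is deterministic and respects the composition", {
  cfg <- synthetic_study_config(n_images = c(glaucoma = 3, dr = 2, normal = 1),
                                seed = 19)
  recs <- generate_study(cfg)
  expect_length(recs, 6)
  expect_equal(as.numeric(table(vapply(recs, `[[`, "", "condition"))[
    c("dr", "glaucoma", "normal")]), c(2, 3, 1))
  expect_true(all(vapply(recs, function(r)
    all(c("ground_truth", "od1", "od2") %in% names(r$tracings)), logical(1))))
  # byte-identical reruns
  recs2 <- generate_study(cfg)
  expect_identical(recs, recs2)
  # a different seed changes at least one tracing
  recs3 <- generate_study(synthetic_study_config(
    n_images = c(glaucoma = 3, dr = 2, normal = 1), seed = 20))
  expect_false(identical(recs, recs3))
  # datasets follow the condition map
  expect_true(all(vapply(recs, function(r)
    r$dataset == ifelse(r$condition == "dr", "aria", "drishti"), logical(1))))
})

test_that("expected mu_d increases monotonically with jitter sd", {
  mus <- vapply(c(1, 2, 4), function(s) {
    cfg <- tiny_config(n = 15, seed = 300, observers = list(
      od1 = observer_model(radial_jitter_sd = s, misalignment_prob = 0,
                           smoothing_window = 1),
      od2 = zero_observer()))
    recs <- generate_study(cfg)
    mean(vapply(recs, function(r) {
      m <- polyline_to_mask(r$tracings$od1, r$shape)
      average_boundary_distance(r$tracings$ground_truth, m)$mu_d
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("glaucoma sector bias lowers border agreement for glaucoma images", {
  base_obs <- function(bias) list(
    od1 = observer_model(radial_jitter_sd = 1, misalignment_prob = 0,
                         sector_bias = if (bias) list(c(60, 120, 5),
                                                      c(240, 300, 5))),
    od2 = observer_model(radial_jitter_sd = 1, misalignment_prob = 0,
                         sector_bias = if (bias) list(c(70, 130, 8),
                                                      c(250, 310, 8))))
  run_one <- function(bias) {
    cfg <- synthetic_study_config(
      n_images = c(glaucoma = 12, dr = 0, normal = 0),
      perturbation = c(glaucoma = 0, dr = 0, normal = 0),
      observers = base_obs(bias), seed = 71)
    recs <- generate_study(cfg)
    mean(vapply(recs, function(r) {
      a <- polyline_to_mask(r$tracings$od1, r$shape)
      b <- polyline_to_mask(r$tracings$od2, r$shape)
      border_kappa(a, b)$kappa
    }, numeric(1)))
  }
  expect_lt(run_one(TRUE), run_one(FALSE))
})
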