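test_that("union_bounding_box is tight, merges masks, and clips margins", {
  m <- matrix(FALSE, 20, 20)
  m[(4:6) + 1, (9:11) + 1] <- TRUE  # rows 4-6 (y), cols 9-11 (x), 0-based
  bb <- union_bounding_box(m)
  expect_equal(unclass(bb)[c("x_min", "y_min", "x_max", "y_max")],
               list(x_min = 9, y_min = 4, x_max = 11, y_max = 6))
  m2 <- matrix(FALSE, 20, 20); m2[16, 2] <- TRUE  # y=15, x=1
  bb2 <- union_bounding_box(list(m, m2))
  expect_equal(c(bb2$x_min, bb2$y_min, bb2$x_max, bb2$y_max), c(1, 4, 11, 15))
  bb3 <- union_bounding_box(m, margin = 100)
  expect_equal(c(bb3$x_min, bb3$y_min, bb3$x_max, bb3$y_max), c(0, 0, 19, 19))
  expect_error(union_bounding_box(matrix(FALSE, 3, 3)), "empty")
})

test_that("region kappa matches the contingency-table oracle on random masks", {
  set.seed(2024)
  for (i in 1:100) {
    a <- matrix(runif(32 * 32) > runif(1, 0.2, 0.8), 32, 32)
    b <- matrix(runif(32 * 32) > runif(1, 0.2, 0.8), 32, 32)
    if (!any(a) && !any(b)) next
    bb <- union_bounding_box(list(a, b))
    expect_equal(region_kappa(a, b, bb)$kappa, oracle_kappa(a, b, bb),
                 tolerance = 1e-12)
  }
})

test_that("region kappa hits its closed-form anchors", {
  m <- disc_mask(40)
  r <- region_kappa(m, m)
  expect_equal(r$kappa, 1)
  expect_equal(r$p_observed, 1)
  # exact complements at p = 0.5
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  bb <- union_bounding_box(list(a, !a))
  r2 <- region_kappa(a, !a, bb)
  expect_equal(r2$kappa, -1)
  expect_equal(r2$p_observed, 0)
  expect_equal(r2$p_expected, 0.5)
  # degenerate: both masks fill the whole box -> Pe = 1, kappa defined as 1
  full <- matrix(TRUE, 4, 4)
  expect_equal(region_kappa(full, full)$kappa, 1)
})

test_that("kappas and dice are symmetric; metrics are translation-invariant", {
  set.seed(9)
  a <- disc_mask(45, 95, 100)
  b <- disc_mask(40, 105, 102)
  bb <- union_bounding_box(list(a, b))
  expect_equal(region_kappa(a, b, bb)$kappa, region_kappa(b, a, bb)$kappa)
  expect_equal(border_kappa(a, b, bb)$kappa, border_kappa(b, a, bb)$kappa)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  # joint translation by (+7, +5)
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  a2 <- shift(a, 5, 7); b2 <- shift(b, 5, 7)
  bb2 <- union_bounding_box(list(a2, b2))
  expect_equal(region_kappa(a2, b2, bb2)$kappa,
               region_kappa(a, b, bb)$kappa, tolerance = 1e-12)
  expect_equal(dice_coefficient(a2, b2), dice_coefficient(a, b))
  expect_equal(average_boundary_distance(a2, b2)$mu_d,
               average_boundary_distance(a, b)$mu_d, tolerance = 1e-9)
})

test_that("border kappa separates offset borders and tracks overlap", {
  m50 <- disc_mask(50); m40 <- disc_mask(40); m49 <- disc_mask(49)
  expect_equal(border_kappa(m50, m50)$kappa, 1)
  bb <- union_bounding_box(list(m50, m40))
  k40 <- border_kappa(m50, m40, bb, tolerance = 2)
  # disjoint bands: chance-level agreement, verified against the oracle
  expect_equal(k40$kappa,
               oracle_kappa(boundary_band(m50, 2), boundary_band(m40, 2), bb),
               tolerance = 1e-12)
  expect_lt(abs(k40$kappa), 0.25)
  k49 <- border_kappa(m50, m49, union_bounding_box(list(m50, m49)),
                      tolerance = 2)
  expect_gt(k49$kappa, k40$kappa)
})

test_that("dice matches its arithmetic definition", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE   # |A| = 100
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE   # |B| = 100, overlap 50
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  c2 <- matrix(FALSE, 20, 20); c2[16:20, 16:20] <- TRUE
  expect_equal(dice_coefficient(a, c2), 0)
  expect_error(dice_coefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
               "empty")
})

test_that("centroid is the foreground mean in (x, y) order", {
  m <- matrix(FALSE, 10, 12); m[1:5, 1:10] <- TRUE  # rows 0-4, cols 0-9
  expect_equal(unname(mask_centroid(m)), c(4.5, 2.0))
  one <- matrix(FALSE, 10, 10); one[4, 8] <- TRUE   # y = 3, x = 7
  expect_equal(unname(mask_centroid(one)), c(7, 3))
  expect_equal(unname(mask_centroid(disc_mask(40, 50, 50, 101))), c(50, 50),
               tolerance = 0.1)
})

test_that("radial distance follows circle, corner, and farthest-pixel rules", {
  m <- disc_mask(40, 100, 100)
  expect_equal(radial_distance(m, c(100, 100), c(0, 45, 90, 135, 270)),
               rep(40, 5), tolerance = 0.5)
  sq <- matrix(FALSE, 201, 201); sq[(90:110) + 1, (90:110) + 1] <- TRUE
  expect_equal(radial_distance(sq, c(100, 100), 45), 10 * sqrt(2),
               tolerance = 0.5)
  # detached misaligned arc beyond the disc edge: farthest pixel wins
  arc <- disc_mask(45, 100, 100)
  arc[(100 - round(60 * sin(seq(80, 100, by = 0.25) * pi / 180))) + 1,
      (100 + round(60 * cos(seq(80, 100, by = 0.25) * pi / 180))) + 1] <- TRUE
  expect_equal(radial_distance(arc, c(100, 100), 90), 60, tolerance = 0.5)
  expect_equal(radial_distance(arc, c(100, 100), 270), 45, tolerance = 0.5)
  # no foreground on the ray -> NA marker
  off <- matrix(FALSE, 50, 50); off[40:45, 40:45] <- TRUE
  expect_true(is.na(radial_distance(off, c(5, 5), 180)))
})

test_that("average boundary distance matches symmetry closed forms", {
  m50 <- disc_mask(50); m40 <- disc_mask(40)
  expect_equal(average_boundary_distance(m50, m50)$mu_d, 0)
  prof <- average_boundary_distance(m50, m40)
  expect_equal(prof$mu_d, 10, tolerance = 0.5)
  expect_equal(prof$n_valid, 12)
  expect_true(all(abs(abs(prof$d_ref - prof$d_test) - 10) <= 0.5))
})

test_that("mu_d is deliberately asymmetric: the reference supplies the centroid", {
  ref <- disc_mask(40, 100, 100)
  test <- disc_mask(40, 130, 100)  # same size, offset center
  a <- average_boundary_distance(ref, test)
  b <- average_boundary_distance(test, ref)
  expect_false(isTRUE(all.equal(a$center, b$center)))
  expect_gt(abs(a$mu_d), 0)
})

test_that("an arc displacement registers in exactly one default direction", {
  ref <- disc_mask(50)
  test <- arc_disc_mask(50, 58, 75, 105)  # 30-degree arc around 90
  prof <- average_boundary_distance(ref, test)
  affected <- abs(prof$d_test - prof$d_ref) > 4
  expect_equal(sum(affected), 1)
  expect_equal(prof$angles[affected], 90)
  # analytic oracle from the polar construction: d differs by 8 on
  # [75, 105) and 0 elsewhere, so on the 12-angle grid mu_d = 8/12
  r_true <- ifelse(prof$angles >= 75 & prof$angles < 105, 58, 50)
  expect_equal(prof$mu_d, mean(abs(r_true - 50)), tolerance = 0.5)
})

test_that("kappa interpretation bands follow the conventional cut-offs", {
  expect_equal(interpret_kappa(0.87), "almost-perfect")
  expect_equal(interpret_kappa(0.21), "fair")
  expect_equal(interpret_kappa(-0.1), "less-than-chance")
  expect_equal(interpret_kappa(c(0.1, 0.5, 0.7, 1.0)),
               c("poor", "moderate", "substantial", "almost-perfect"))
  expect_error(interpret_kappa(1.2), "exceed")
})
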