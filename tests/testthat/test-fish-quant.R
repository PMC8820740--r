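test_that("a flat nuclei band yields a near-constant fitted boundary", {
  set.seed(81)
  # nuclei fill y < 100 (cell bodies on the low side)
  fld <- flat_field(100, cb_side = "low")
  cv <- estimate_boundary(fld, degree = 1)
  xs <- seq(cv$x_range[1], cv$x_range[2], length.out = 50)
  ys <- poly_eval(cv$coeffs, xs)
  expect_lt(max(abs(ys - 100)), 2.5)   # within half a smoothing bandwidth

  # flipped orientation: nuclei fill y > c
  fld2 <- flat_field(100, cb_side = "high")
  cv2 <- estimate_boundary(fld2, degree = 1, cb_side = "high")
  ys2 <- poly_eval(cv2$coeffs, xs)
  expect_lt(max(abs(ys2 - 100)), 2.5)
})

test_that("an aberrant slice anchor is removed by the residual rule", {
  set.seed(82)
  fld <- flat_field(100, shift_slice = 13, shift_by = 50)
  cv <- estimate_boundary(fld, degree = 1)
  expect_gte(cv$n_outliers, 1)
  expect_false(all(cv$anchors$kept))
  expect_lt(cv$sd_round2, cv$sd_round1)
  # the shifted anchor is the one that was dropped
  dropped <- cv$anchors[!cv$anchors$kept, ]
  expect_true(any(dropped$y < 80))
})

test_that("boundary recovery on curved synthetic fields is accurate", {
  rms <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s)
    f <- gen_fish_field(cfg)
    cv <- estimate_boundary(f)
    xs <- seq(cv$x_range[1], cv$x_range[2], length.out = 200)
    sqrt(mean((poly_eval(cv$coeffs, xs) -
                 poly_eval(cfg$fish_boundary_coeffs, xs))^2))
  }, numeric(1))
  expect_lt(max(rms), 2)
})

test_that("spot distances are exact for flat and quadratic boundaries", {
  flat <- structure(list(coeffs = c(100), degree = 0, x_range = c(0, 200),
                         cb_side = "low"), class = "boundary_curve")
  sp <- data.frame(x_um = c(50, 70, 30), y_um = c(107, 100, 93))
  d <- spot_distances(sp, flat)
  expect_equal(d$distance, c(7, 0, -7), tolerance = 1e-6)

  quad <- structure(list(coeffs = c(80, 0.3, -0.002), degree = 2,
                         x_range = c(0, 150), cb_side = "low"),
                    class = "boundary_curve")
  set.seed(83)
  sp2 <- data.frame(x_um = runif(40, 0, 150), y_um = runif(40, 40, 160))
  got <- spot_distances(sp2, quad)$distance
  # fine-grid brute-force minimizer at 0.01 um
  xg <- seq(0, 150, by = 0.01)
  yg <- poly_eval(quad$coeffs, xg)
  oracle <- vapply(seq_len(nrow(sp2)), function(i) {
    dmin <- sqrt(min((sp2$x_um[i] - xg)^2 + (sp2$y_um[i] - yg)^2))
    sgn <- if (sp2$y_um[i] > poly_eval(quad$coeffs, sp2$x_um[i])) 1 else -1
    dmin * sgn
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 0.1)

  # out-of-range spots take the endpoint distance and are flagged
  far <- spot_distances(data.frame(x_um = -10, y_um = 100), flat)
  expect_true(far$out_of_range)
  expect_equal(abs(far$distance), sqrt(100), tolerance = 1e-6)
})

test_that("spot classification is strict at 10 um and order-invariant", {
  d <- data.frame(x_um = 1:3, y_um = 1, distance = c(10.0, 10.1, 20),
                  image_id = "i")
  cs <- classify_spots(d)
  expect_equal(cs$spots$compartment, c("cell-body", "neuropil", "neuropil"))
  all20 <- classify_spots(data.frame(distance = rep(20, 5),
                                     image_id = "i"))
  expect_equal(all20$fractions$neuropil_fraction, 1)
  perm <- classify_spots(d[c(3, 1, 2), ])
  expect_equal(perm$fractions$neuropil_fraction,
               cs$fractions$neuropil_fraction)
})

test_that("translation invariance and reflection antisymmetry hold", {
  set.seed(84)
  cfg <- sim_config(fish_n_spots = 300L, seed = 85)
  f <- gen_fish_field(cfg)
  cv <- estimate_boundary(f)
  d0 <- spot_distances(f$spots, cv)$distance
  # translate everything by (dx, dy)
  f2 <- f
  dx <- 12; dy <- -9
  f2$nuclei_px$col <- f2$nuclei_px$col + dx / f$um_per_px
  f2$nuclei_px$row <- f2$nuclei_px$row + dy / f$um_per_px
  f2$spots$x_um <- f2$spots$x_um + dx
  f2$spots$y_um <- f2$spots$y_um + dy
  cv2 <- estimate_boundary(f2)
  d2 <- spot_distances(f2$spots, cv2)$distance
  expect_equal(d2, d0, tolerance = 0.2)
  # reflecting spots across the fitted curve flips the sign
  refl <- f$spots
  refl$y_um <- 2 * poly_eval(cv$coeffs, refl$x_um) - refl$y_um
  dr <- spot_distances(refl, cv)$distance
  expect_equal(dr, -d0, tolerance = 0.2)
})

test_that("probe-distribution comparisons expose KS and Wilcoxon results", {
  set.seed(86)
  x <- rnorm(50); y <- rnorm(50)
  same <- compare_probe_distributions(x, x)
  expect_equal(same$ks_D, 0)
  expect_equal(same$ks_p, 1)
  r <- compare_probe_distributions(x, y + 3,
                                   fractions_a = c(0.1, 0.2, 0.15),
                                   fractions_b = c(0.6, 0.7, 0.65))
  expect_lt(r$ks_p, 1e-6)
  expect_true(r$wilcox_p < 0.2)
  expect_error(compare_probe_distributions(x[1:3], y), "at least 5")
})

test_that("small-sample Wilcoxon matches full rank enumeration", {
  # all 20 assignments of ranks {1..6} to group A of size 3
  combos <- combn(6, 3)
  w_obs <- sum(c(1, 2, 3))
  w_null <- apply(combos, 2, sum)
  p_one <- mean(w_null <= w_obs)
  expect_equal(p_one, 1 / 20)
  expect_equal(wilcox.test(c(1, 2, 3), c(4, 5, 6),
                           alternative = "less")$p.value, p_one)
  expect_equal(wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value, 2 / 20)
})

test_that("binned genotype comparison conserves percentages and its seed", {
  set.seed(87)
  dt <- data.frame(image_id = rep(paste0("i", 1:8), each = 400),
                   distance = runif(3200, 0, 150))
  gt <- setNames(rep(c("WT", "KO"), each = 4), paste0("i", 1:8))
  suppressMessages({
    r1 <- binned_wt_ko_comparison(dt, gt, n_sample = 300, seed = 5)
    r2 <- binned_wt_ko_comparison(dt, gt, n_sample = 300, seed = 5)
  })
  expect_identical(r1, r2)
  expect_equal(sum(r1$mean_WT), 100, tolerance = 1e-9)
  expect_equal(sum(r1$mean_KO), 100, tolerance = 1e-9)
  expect_error(binned_wt_ko_comparison(dt[dt$image_id %in%
                                            c("i1", "i5"), ],
                                       gt, n_sample = 10), "at least 2")
})

test_that("binned comparison holds its size under the null", {
  set.seed(88)
  hits <- replicate(200, {
    dt <- data.frame(image_id = rep(paste0("i", 1:8), each = 200),
                     distance = rexp(1600, 1 / 40))
    gt <- setNames(rep(c("WT", "KO"), each = 4), paste0("i", 1:8))
    r <- suppressMessages(
      binned_wt_ko_comparison(dt, gt, n_sample = 200,
                              seed = sample.int(1e6, 1)))
    mean(r$p < 0.05, na.rm = TRUE)
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})
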