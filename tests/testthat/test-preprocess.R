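raw_constant <- function(value = 80, ...) {
  thickness_map(matrix(value, 128, 512), ...)
}

test_that("thickness extraction multiplies boundary separation by the axial scale", {
  up <- matrix(100, 4, 6); lo <- matrix(150, 4, 6)
  tm <- thickness_from_boundaries(up, lo, axial_scale_um = 1.95)
  expect_true(all(tm$values == 97.5))

  z <- thickness_from_boundaries(up, up)
  expect_true(all(z$values == 0))

  err <- matrix(FALSE, 4, 6); err[, 3] <- TRUE
  tm2 <- thickness_from_boundaries(up, lo, axial_scale_um = 1.95, erroneous = err)
  expect_true(all(!tm2$valid[, 3]))
  expect_true(all(tm2$valid[, -3]))
  expect_true(all(tm2$values[, -3] == 97.5))

  lo2 <- lo; lo2[2, 4] <- 90
  expect_error(thickness_from_boundaries(up, lo2), "row 2, col 4")
})

test_that("bicubic resize reproduces constants and linear ramps", {
  cm <- resize_map(raw_constant(42))
  expect_equal(dim(cm$values), c(512, 512))
  expect_lt(max(abs(cm$values - 42)), 1e-9)

  ramp <- thickness_map(matrix(0:127, 128, 512))
  rr <- resize_map(ramp)
  s <- pmin(pmax((seq_len(512) - 0.5) * 128 / 512 - 0.5, 0), 127)
  err <- abs(rr$values[, 1] - s)
  # rows whose 4-tap support touches the replicated border (source position
  # within one sample of either end) are excluded; the interior is exact
  expect_lt(max(err[8:504]), 1e-6)
  expect_lt(max(err), 0.1)          # border-clamp error stays sub-pixel

  expect_error(resize_map(thickness_map(matrix(1, 64, 64))), "512")
})

test_that("resize erodes validity so invalid pixels never contribute", {
  v <- matrix(50, 128, 512)
  ok <- matrix(TRUE, 128, 512); ok[60, 100] <- FALSE
  v[60, 100] <- NA
  rm <- resize_map(thickness_map(v, valid = ok))
  # rows fed by source row 60 (0-based 59) become invalid in that column
  expect_false(all(rm$valid[, 100]))
  expect_true(all(rm$valid[, -100]))
  expect_lt(sum(!rm$valid), 30)
})

test_that("right-eye conversion mirrors OS maps and is an involution", {
  od <- raw_constant(10, laterality = "OD")
  expect_identical(orient_right_eye(od)$values, od$values)

  v <- matrix(1, 128, 512); v[30, 11] <- 99  # marker at 0-based column 10
  os <- thickness_map(v, laterality = "OS", tilt_deg = 4)
  m <- orient_right_eye(os)
  expect_equal(which(m$values[30, ] == 99) - 1, 501)  # 511 - 10
  expect_equal(m$tilt_deg, -4)
  back <- m; back$laterality <- "OS"
  expect_identical(orient_right_eye(back)$values, os$values)
})

test_that("tilt rotation moves landmarks by minus the tilt about the fovea", {
  sq <- matrix(100, 512, 512)
  zero <- thickness_map(sq, tilt_deg = 0)
  expect_lt(max(abs(rotate_to_zero_tilt(zero)$values - 100)), 1e-9)

  # rotationally symmetric map is unchanged within interpolation tolerance
  f <- 255.5
  r <- sqrt(outer((0:511 - f)^2, (0:511 - f)^2, "+"))
  sym <- thickness_map(50 + 20 * cos(r / 40), tilt_deg = 11)
  rs <- rotate_to_zero_tilt(sym)
  expect_lt(max(abs(rs$values - sym$values)[rs$valid]), 1e-3)

  # point landmark at 45 deg polar angle ends at 38 deg after a 7 deg tilt
  v <- matrix(100, 512, 512)
  rad <- 150
  x0 <- f + rad * cos(45 * pi / 180)
  y0 <- f - rad * sin(45 * pi / 180)
  v[round(y0) + 1, round(x0) + 1] <- 500
  lm <- rotate_to_zero_tilt(thickness_map(v, tilt_deg = 7))
  peak <- which(lm$values == max(lm$values, na.rm = TRUE), arr.ind = TRUE)
  px <- peak[1, 2] - 1; py <- peak[1, 1] - 1
  ang <- atan2(f - py, px - f) * 180 / pi
  expect_lt(abs(ang - 38), atan2(0.5, rad) * 180 / pi + 0.2)
  expect_equal(unname(sqrt((px - f)^2 + (py - f)^2)), rad, tolerance = 1)
})

test_that("displacement correction resamples radially per the profile", {
  m <- thickness_map(matrix(75, 512, 512))
  p0 <- displacement_profile(c(0, 5, 10), c(0, 0, 0))
  expect_lt(max(abs(apply_displacement_correction(m, p0)$values - 75)), 1e-9)

  # constant maps are invariant under any profile
  p1 <- displacement_profile(c(0, 2, 4, 8), c(0, 1, 0.5, 0))
  expect_lt(max(abs(apply_displacement_correction(m, p1)$values[
    apply_displacement_correction(m, p1)$valid] - 75)), 1e-9)

  # a pixel at 2 deg eccentricity reads the source value at 3 deg (outward)
  f <- 255.5; px_mm <- 6 / 512
  ecc_mm <- sqrt(outer((0:511 - f)^2, (0:511 - f)^2, "+")) * px_mm
  ecc_deg <- t(ecc_mm) / 0.288
  v <- thickness_map(50 + 10 * ecc_deg)  # linear in eccentricity (deg)
  p2 <- displacement_profile(c(0, 2, 4), c(0, 1, 0))
  out <- apply_displacement_correction(v, p2)
  probe <- which(abs(ecc_deg - 2) < 0.005 & out$valid, arr.ind = TRUE)
  expect_gt(nrow(probe), 0)
  expect_equal(mean(out$values[probe]), 50 + 10 * 3, tolerance = 0.05)

  expect_error(apply_displacement_correction(m, list()), "displacement_profile")
})

test_that("standardisation inverts the generator's native orientation", {
  d <- defect_spec(hemifields = "superior_retina", gcipl_depth = 15)
  m <- quiet_model("GCIPL")
  a <- synth_thickness_map(flat_record(eye = "OD", tilt = 5), m, defect = d, seed = 1)
  b <- synth_thickness_map(flat_record(eye = "OS", tilt = -3), m, defect = d, seed = 1)
  sa <- standardise_map(a)
  sb <- standardise_map(b)
  # same standard-frame content: agreement within 0.5 um on the central 80%
  # of pixels, allowing the sharp defect border (~1% of pixels) where
  # resampling a binary edge differs legitimately between the two paths
  ctr <- 52:461
  diff <- abs(sa$values - sb$values)[ctr, ctr]
  ok0 <- sa$valid & sb$valid
  ok <- ok0[ctr, ctr]
  expect_gt(mean(ok), 0.99)
  expect_lt(stats::quantile(diff[ok], 0.95), 0.5)
  expect_lt(stats::median(diff[ok]), 0.05)
  # and the deep defect regions coincide almost exactly
  deep_a <- sa$values < 40 & ok0; deep_b <- sb$values < 40 & ok0
  expect_gt(2 * sum(deep_a & deep_b, na.rm = TRUE) /
              (sum(deep_a, na.rm = TRUE) + sum(deep_b, na.rm = TRUE)), 0.97)
  expect_equal(sa$tilt_deg, 0)
  expect_equal(sb$laterality, "OD")
})

test_that("valid-pixel count never increases along the pipeline", {
  v <- matrix(60, 128, 512)
  ok <- matrix(TRUE, 128, 512); ok[, sample(512, 10)] <- FALSE
  v[!ok] <- NA
  m <- thickness_map(v, valid = ok, laterality = "OS", tilt_deg = 6)
  n0 <- sum(m$valid)
  r1 <- resize_map(m);            expect_lte(sum(r1$valid) / 4, n0)
  r2 <- orient_right_eye(r1);     expect_lte(sum(r2$valid), sum(r1$valid))
  r3 <- rotate_to_zero_tilt(r2);  expect_lte(sum(r3$valid), sum(r2$valid))
  prof <- displacement_profile(c(0, 2, 4), c(0, 1, 0))
  r4 <- apply_displacement_correction(r3, prof)
  expect_lte(sum(r4$valid), sum(r3$valid))
})

test_that("scan metadata XML stub parses", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c("<scan>", "  <fovea_x>255.5</fovea_x>", "  <fovea_y>63.5</fovea_y>",
               "  <laterality>OS</laterality>", "  <tilt_deg>6.4</tilt_deg>",
               "</scan>"), xml)
  md <- read_scan_metadata(xml)
  expect_equal(md$fovea_xy, c(255.5, 63.5))
  expect_equal(md$laterality, "OS")
  expect_equal(md$tilt_deg, 6.4)
})
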