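test_that("demographic sampling is deterministic and respects its ranges", {
  spec <- demographics_spec(n = 3, seed = 1)
  expect_identical(sample_demographics(spec), sample_demographics(spec))

  deg <- demographics_spec(n = 10, age_range = c(50, 50), seed = 2)
  expect_true(all(sample_demographics(deg)$age == 50))

  spec <- demographics_spec(n = 200, age_range = c(30, 70), se_range = c(-3, 1),
                            seed = 5)
  d <- sample_demographics(spec)
  expect_true(all(d$age >= 30 & d$age <= 70))
  expect_true(all(d$se >= -3 & d$se <= 1))
  expect_true(all(d$sex %in% c("M", "F")))
})

test_that("sampled sex ratio stays inside binomial 99% bounds", {
  spec <- demographics_spec(n = 548, sex_ratio = 0.45, seed = 7)
  d <- sample_demographics(spec)
  lo <- qbinom(0.005, 548, 0.45) / 548
  hi <- qbinom(0.995, 548, 0.45) / 548
  frac <- mean(d$sex == "M")
  expect_gte(frac, lo)
  expect_lte(frac, hi)
})

test_that("noise-free maps equal the baseline profile plus linear effects", {
  m <- quiet_model("GCIPL")
  ref <- synth_thickness_map(flat_record(age = m$ref_age, sex = "F", se = 0),
                             m, seed = 1)
  # pixel (row 64, col 256) sits just off the foveal centre (pixel-centre grid)
  ecc <- sqrt(((255 - 255.5) * 6 / 512)^2 + ((63.5 - 63) * 6 / 128)^2)
  prof <- approx(m$baseline_profile$ecc_mm, m$baseline_profile$thickness_um,
                 xout = ecc, rule = 2)$y
  expect_equal(ref$values[64, 256], prof, tolerance = 1e-9)

  # age slope: 20 years at -0.112 um/y shifts the whole map by 2.24 um
  m2 <- quiet_model("GCIPL", age_slope = -0.112)
  m40 <- synth_thickness_map(flat_record(age = 40), m2, seed = 1)
  m60 <- synth_thickness_map(flat_record(age = 60), m2, seed = 1)
  expect_equal(mean(m40$values - m60$values), 20 * 0.112, tolerance = 1e-9)
})

test_that("planted defects are additive, linear and layer-coupled", {
  d10 <- defect_spec(hemifields = "superior_retina", gcipl_depth = 10,
                     inl_ratio = 0.3, vf_depth = 8)
  d20 <- defect_spec(hemifields = "superior_retina", gcipl_depth = 20,
                     inl_ratio = 0.3, vf_depth = 8)
  m <- quiet_model("GCIPL")
  base <- synth_thickness_map(flat_record(), m, seed = 1)
  def <- synth_thickness_map(flat_record(), m, defect = d10, seed = 1)
  diff <- base$values - def$values
  expect_true(all(diff %in% c(0, 10)))
  expect_gt(sum(diff == 10), 0)

  def2 <- synth_thickness_map(flat_record(), m, defect = d20, seed = 1)
  expect_equal(base$values - def2$values, 2 * diff, tolerance = 1e-12)

  # INL deficit is exactly inl_ratio times the GCIPL deficit inside the mask
  mi <- quiet_model("INL")
  bi <- synth_thickness_map(flat_record(), mi, seed = 1)
  di <- synth_thickness_map(flat_record(), mi, defect = d10, seed = 1)
  inl_deficit <- bi$values - di$values
  expect_equal(mean(inl_deficit[diff == 10]), 0.3 * 10, tolerance = 1e-12)
})

test_that("map synthesis is reproducible under a fixed seed", {
  m <- layer_effect_model("ORC", noise_sd = 2, between_subject_sd = 2,
                          profile_scale_sd = 0.02)
  a <- synth_thickness_map(flat_record(), m, seed = 9)
  b <- synth_thickness_map(flat_record(), m, seed = 9)
  expect_identical(a$values, b$values)
})

test_that("synthetic visual fields follow the planted defect arithmetic", {
  clean <- synth_vf(NULL, noise_sd = 0, seed = 1)
  expect_equal(nrow(clean$points), 68)
  expect_true(all(clean$points$pd == 0))
  expect_equal(clean$md, 0)
  expect_equal(clean$psd, 0)
  expect_true(all(clean$points$prob == "none"))

  d <- defect_spec(hemifields = "inferior_retina", gcipl_depth = 10,
                   vf_depth = 8)
  vf <- synth_vf(d, noise_sd = 0, seed = 1)
  flagged <- vf$points$prob != "none"
  expect_true(all(vf$points$y[flagged] > 0))  # superior VF defect
  k <- sum(flagged)
  expect_gt(k, 0)
  expect_equal(vf$md, -8 * k / 68, tolerance = 1e-12)
  expect_true(all(vf$points$pd[flagged] == -8))

  expect_identical(synth_vf(d, 0.5, seed = 3)$points,
                   synth_vf(d, 0.5, seed = 3)$points)
})

test_that("the 10-2 lattice has the standard shape", {
  lat <- vf_lattice_10_2()
  expect_equal(nrow(lat), 68)
  expect_true(all(lat$x %% 2 == 1 | lat$x %% 2 == -1))
  expect_true(all(abs(lat$x) <= 9 & abs(lat$y) <= 9))
  expect_equal(as.vector(table(lat$y)), c(2, 6, 8, 8, 10, 10, 8, 8, 6, 2))
})

test_that("cohort simulation is deterministic and carries defects", {
  spec <- demographics_spec(n = 2, seed = 4, tilt_sd = 1)
  d <- defect_spec(gcipl_depth = 5)
  c1 <- simulate_cohort(spec, models = list(GCIPL = quiet_model("GCIPL")),
                        defect_fn = d, vf = TRUE)
  c2 <- simulate_cohort(spec, models = list(GCIPL = quiet_model("GCIPL")),
                        defect_fn = d, vf = TRUE)
  expect_identical(c1[[1]]$maps$GCIPL$values, c2[[1]]$maps$GCIPL$values)
  expect_identical(c1[[2]]$vf$points, c2[[2]]$vf$points)
  expect_s3_class(c1[[1]]$defect, "defect_spec")
})
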