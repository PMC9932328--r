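test_that("phantom rasterization is deterministic under a fixed seed", {
  a <- tiny_tube(noise_sd = 20, seed = 7)
  b <- tiny_tube(noise_sd = 20, seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  c <- tiny_tube(noise_sd = 20, seed = 8)
  expect_false(identical(a$volume$data, c$volume$data))
  # the generator must not disturb the session RNG
  set.seed(99); before <- .Random.seed
  tiny_tube(noise_sd = 5, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("rasterized lumen volume converges to the analytic cylinder volume", {
  # lumen-only contrast (wall at background HU) makes the partial-volume
  # fraction recoverable from HU: frac = (bg - hu) / (bg - lumen)
  lumen <- 4; len <- 16
  spec <- straight_tube_spec(lumen_mm = lumen, wall_mm = 1, length_mm = len,
                             wall_hu = -850, background_hu = -850)
  spacing <- (lumen / 2) / 4  # radius / 4
  ph <- make_airway_phantom(spec, spacing = spacing)
  frac <- (-850 - ph$volume$data) / (-850 - -1000)
  # restrict to an interior slab clear of the rounded tube ends, where the
  # phantom is a pure cylinder
  z <- ph$volume$origin[3] + (seq_len(dim(frac)[3]) - 1) * spacing
  slab <- z >= lumen / 2 + spacing & z <= len - lumen / 2 - spacing
  vol <- sum(frac[, , slab]) * voxel_volume_mm3(ph$volume)
  want <- pi * (lumen / 2)^2 * (sum(slab) * spacing)
  expect_lt(abs(vol - want) / want, 0.05)
})

test_that("branches outside an explicit grid are rejected", {
  spec <- straight_tube_spec(lumen_mm = 4, wall_mm = 1, length_mm = 30)
  expect_error(
    make_airway_phantom(spec, spacing = 0.5, shape = c(20, 20, 20),
                        origin = c(-5, -5, -5)),
    "outside"
  )
  expect_error(make_airway_phantom(spec, spacing = -0.5), "positive")
})

test_that("planted defect fractions are recorded exactly as counted", {
  geo <- small_lobe_geometry()
  sp <- trapping_spec(defect_fraction = c(RML = 0.10, LLL = 0.05), seed = 3)
  ph <- make_paired_lung_phantom(geo, sp)
  ff <- ph$defect_fractions
  for (i in seq_len(nrow(ff))) {
    lobe_sel <- geo$data == lobe_labels()[[ff$region[i]]]
    counted <- sum(ph$defect_mask & lobe_sel) / sum(lobe_sel)
    expect_identical(ff$realized_fraction[i], counted)
  }
  rml <- ff[ff$region == "RML", ]
  expect_lt(abs(rml$realized_fraction - 0.10), 0.01)
  # no defect voxel may cross its lobe border into another region
  expect_true(all(geo$data[ph$defect_mask] > 0))
})

test_that("zero defect fraction leaves the expiratory distribution pure", {
  geo <- small_lobe_geometry()
  ph <- make_paired_lung_phantom(geo, trapping_spec(defect_fraction = 0,
                                                    seed = 5))
  expect_equal(sum(ph$defect_mask), 0)
  lung <- ph$exp$data[geo$data > 0]
  # all expiratory voxels from the N(-650, 50) normal-tissue distribution
  expect_lt(abs(mean(lung) - -650), 3 * 50 / sqrt(length(lung)))
})

test_that("unreachable blob targets raise a generation error", {
  geo <- lobe_block_geometry(shape = c(12, 12, 15))
  sp <- trapping_spec(defect_fraction = 0.4, blob_radius_mm = 20, seed = 1)
  expect_error(make_paired_lung_phantom(geo, sp, max_attempts = 50),
               "unreachable")
})

test_that("trapping spec enforces its physiological invariants", {
  expect_error(trapping_spec(defect_fraction = 1.2), "\\[0, 1\\]")
  expect_error(trapping_spec(insp_mean = -650, exp_mean = -850), "densifies")
  expect_error(trapping_spec(defect_mean = -600, exp_mean = -650), "below")
})

test_that("cohort simulator produces the balanced design", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 36, seed = 2))
  expect_equal(nrow(coh), 36 * 4 * 6)
  counts <- dplyr::count(coh, subject, timepoint_months)
  expect_true(all(counts$n == 6))
  expect_setequal(unique(coh$timepoint_months), c(0, 3, 12, 24))
  # age advances with the visit schedule
  one <- coh[coh$subject == "S001" & coh$region == "RUL", ]
  expect_equal(diff(one$age_years[order(one$timepoint_months)]),
               c(0.25, 0.75, 1))
})

test_that("with all variances zero the endpoint equals the linear predictor", {
  eps <- default_endpoints()
  eps$BEI$sd_patient <- 0; eps$BEI$sd_region <- 0; eps$BEI$sd_resid <- 0
  coh <- simulate_cohort(cohort_truth(n_subjects = 5, endpoints = eps,
                                      seed = 9))
  expect_equal(coh$BEI, coh$.lp_BEI, tolerance = 1e-12)
})

test_that("empirical variance decomposition matches the requested components", {
  eps <- default_endpoints()
  eps$BEI$sd_patient <- 0.3; eps$BEI$sd_region <- 0.2; eps$BEI$sd_resid <- 0.25
  # many subjects, one endpoint: ~10^4 rows
  coh <- simulate_cohort(cohort_truth(n_subjects = 420, endpoints = eps,
                                      seed = 31))
  expect_gte(nrow(coh), 1e4)
  expect_lt(abs(sd(coh$.u_pat_BEI) - 0.3) / 0.3, 0.10)
  expect_lt(abs(sd(coh$.u_reg_BEI) - 0.2) / 0.2, 0.10)
  resid <- coh$BEI - coh$.lp_BEI - coh$.u_pat_BEI - coh$.u_reg_BEI
  expect_lt(abs(sd(resid) - 0.25) / 0.25, 0.10)
})

test_that("cohort CSV round trip keeps the analysis schema", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 3, seed = 1))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, p)
  back <- read_cohort_csv(p)
  expect_named(back, c("subject", "timepoint_months", "age_years", "region",
                       "A3", "BEI", "LA_5_10", "WP_5_10"), ignore.order = TRUE)
  expect_equal(back$BEI, coh$BEI, tolerance = 1e-10)
})
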