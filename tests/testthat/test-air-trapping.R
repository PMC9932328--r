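make_pair <- function(defect_fraction = 0, seed = 1, geo = small_lobe_geometry(),
                      ...) {
  make_paired_lung_phantom(geo, trapping_spec(defect_fraction = defect_fraction,
                                              seed = seed, ...))
}

test_that("region volumes are voxel count times voxel volume", {
  g <- volume_grid(array(-800, c(10, 10, 10)), spacing = 1)
  m <- volume_grid(array(0L, c(10, 10, 10)), spacing = 1)
  m$data[1:10, 1:10, 1:10] <- 0L
  m$data[seq_len(1000)] <- 1L  # 1000 voxels at 1 mm^3
  expect_equal(region_volume(g, m, "RUL"), 1.0)
  expect_error(region_volume(g, m, "RML"), "empty")
  # lobar volumes sum exactly to the total (disjoint labels)
  ph <- make_pair()
  lob <- vapply(names(lobe_labels()), function(r) {
    region_volume(ph$insp, ph$mask, r)
  }, numeric(1))
  expect_equal(sum(lob), region_volume(ph$insp, ph$mask, "total"))
})

test_that("RVC is zero on identical paired volumes and -1 at full band shift", {
  ph <- make_pair()
  expect_equal(compute_rvc(ph$insp, ph$insp, ph$mask, ph$mask), 0)
  # inspiration entirely inside [-950, -856]; expiration entirely above -856
  g <- ph$mask
  insp <- volume_grid(array(-900, dim(g$data)), g$spacing)
  exp_ <- volume_grid(array(-700, dim(g$data)), g$spacing)
  expect_equal(compute_rvc(insp, exp_, g, g), -1)
})

test_that("RVC on two-Gaussian phantoms matches the analytic band difference", {
  ph <- make_pair(seed = 17, geo = lobe_block_geometry(c(40, 40, 48)))
  got <- compute_rvc(ph$insp, ph$exp, ph$mask, ph$mask)
  want <- rvc_gaussian_oracle(-850, 50, -650, 50)
  n <- sum(ph$mask$data > 0)
  expect_lt(abs(got - want), 3 * rvc_gaussian_sem(-850, 50, -650, 50, n))
})

test_that("E/I MLA identities and phantom scale", {
  ph <- make_pair()
  expect_equal(compute_ei_mla(ph$insp, ph$insp, ph$mask, ph$mask), 1.0)
  got <- compute_ei_mla(ph$insp, ph$exp, ph$mask, ph$mask)
  n <- sum(ph$mask$data > 0)
  tol <- 3 * ratio_of_means_sem(-650, 50, -850, 50, n, n)
  expect_lt(abs(got - 650 / 850), tol)
})

test_that("patient-specific thresholds interpolate the two attenuations", {
  thr <- derive_at_thresholds(-850, -650)
  expect_equal(unname(thr), c(-700, -750, -800))
  # degenerate equal fractions collapse all three thresholds
  thr_eq <- derive_at_thresholds(-850, -650, fractions = c(0.5, 0.5, 0.5))
  expect_true(all(thr_eq == thr_eq[1]))
  # affine equivariance: shifting both MLAs by c shifts every threshold by c
  shift <- 37
  thr2 <- derive_at_thresholds(-850 + shift, -650 + shift)
  expect_equal(unname(thr2 - thr), rep(shift, 3))
  expect_error(derive_at_thresholds(-650, -850), "non-physiological")
  expect_error(derive_at_thresholds(-850, -650, fractions = c(0.2, 0.5, 0.7)),
               "non-increasing")
})

test_that("defect percentages saturate and nest", {
  ph <- make_pair()
  g <- ph$mask
  # no voxel below T1 -> all zeros
  exp_hi <- volume_grid(array(-600, dim(g$data)), g$spacing)
  a0 <- compute_defects(exp_hi, g, c(-700, -750, -800))
  expect_equal(unname(a0), c(0, 0, 0))
  # all voxels below T3 -> all 100
  exp_lo <- volume_grid(array(-950, dim(g$data)), g$spacing)
  a1 <- compute_defects(exp_lo, g, c(-700, -750, -800))
  expect_equal(unname(a1), c(100, 100, 100))
  expect_error(compute_defects(exp_lo, g, c(-800, -750, -700)),
               "non-increasing")
})

test_that("a planted 10% RML defect is recovered as A3 within 1 point", {
  ph <- make_pair(defect_fraction = c(RML = 0.10), seed = 23,
                  geo = lobe_block_geometry(c(40, 40, 48)))
  at <- air_trapping_table(ph$insp, ph$exp, ph$mask, ph$mask)
  a3_rml <- at$A3[at$region == "RML"]
  expect_lt(abs(a3_rml - 10), 1)
})

test_that("nesting A1 >= A2 >= A3 holds on random paired phantoms", {
  set.seed(77)
  for (seed in 1:25) {
    frac <- stats::setNames(round(runif(6, 0, 0.3), 2), names(lobe_labels()))
    ph <- make_pair(defect_fraction = frac, seed = seed)
    at <- air_trapping_table(ph$insp, ph$exp, ph$mask, ph$mask)
    expect_true(all(at$A1 >= at$A2 & at$A2 >= at$A3))
    expect_true(all(at$A1 <= 100 & at$A3 >= 0))
  }
})

test_that("total-lung defect percentages equal the volume-weighted lobar mean", {
  ph <- make_pair(defect_fraction = c(RML = 0.2, LLL = 0.05), seed = 9)
  at <- air_trapping_table(ph$insp, ph$exp, ph$mask, ph$mask)
  lobes <- at[at$region != "total", ]
  tot <- at[at$region == "total", ]
  w <- lobes$RLV_cm3 / sum(lobes$RLV_cm3)
  for (k in c("A1", "A2", "A3")) {
    expect_equal(tot[[k]], sum(w * lobes[[k]]), tolerance = 1e-10)
  }
})

test_that("histogram metrics are invariant to voxel shuffling within regions", {
  ph <- make_pair(defect_fraction = 0.1, seed = 5)
  shuf <- ph$exp
  set.seed(1)
  sel <- ph$mask$data == lobe_labels()[["RML"]]
  vals <- shuf$data[sel]
  shuf$data[sel] <- sample(vals)
  thr <- c(-700, -750, -800)
  expect_identical(compute_defects(ph$exp, ph$mask, thr, "RML"),
                   compute_defects(shuf, ph$mask, thr, "RML"))
  expect_identical(compute_rvc(ph$insp, ph$exp, ph$mask, ph$mask, "RML"),
                   compute_rvc(ph$insp, shuf, ph$mask, ph$mask, "RML"))
})

test_that("enlarging a planted defect never decreases A_k or RVC", {
  geo <- lobe_block_geometry(c(32, 32, 42))
  prev_a <- c(-Inf, -Inf, -Inf); prev_rvc <- -Inf
  for (f in c(0, 0.05, 0.15, 0.3)) {
    ph <- make_pair(defect_fraction = c(RML = f), seed = 11, geo = geo)
    at <- air_trapping_table(ph$insp, ph$exp, ph$mask, ph$mask)
    rml <- at[at$region == "RML", ]
    a <- c(rml$A1, rml$A2, rml$A3)
    expect_true(all(a >= prev_a - 1e-9))
    expect_gte(rml$RVC, prev_rvc - 1e-9)
    prev_a <- a; prev_rvc <- rml$RVC
  }
})
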