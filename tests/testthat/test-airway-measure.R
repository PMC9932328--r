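test_that("WP, TD and WT are exact functions of LA and WA on emitted measures", {
  # property over random valid sections
  set.seed(12)
  LA <- runif(1000, 1, 60)
  WA <- runif(1000, 0.5, 40)
  TD <- 2 * sqrt((LA + WA) / pi)
  WT <- (TD - 2 * sqrt(LA / pi)) / 2
  WP <- 100 * WA / (LA + WA)
  expect_true(all(WP > 0 & WP < 100))
  # the same identities must hold to machine precision on measured sections
  ph <- tiny_tube()
  m <- measure_cross_section(ph$volume, c(0, 0, 7), c(0, 0, 1))
  expect_true(m$valid)
  expect_equal(m$WP, 100 * m$WA / (m$LA + m$WA), tolerance = 1e-12)
  expect_equal(m$TD, 2 * sqrt((m$LA + m$WA) / pi), tolerance = 1e-12)
  expect_equal(m$WT, (m$TD - 2 * sqrt(m$LA / pi)) / 2, tolerance = 1e-12)
  # LA = WA -> WP = 50 exactly, by the formula
  expect_equal(100 * 5 / (5 + 5), 50)
})

test_that("noise-free 4 mm tube is measured within the stated tolerances", {
  ph <- tiny_tube(lumen_mm = 4, wall_mm = 1, spacing = 0.5)
  m <- measure_cross_section(ph$volume, c(0, 0, 7), c(0, 0, 1))
  expect_true(m$valid)
  expect_lt(abs(m$LA - pi * 2^2) / (pi * 2^2), 0.05)
  expect_lt(abs(m$WT - 1), 0.25)
  expect_lt(abs(2 * sqrt(m$LA / pi) - 4), 0.25)
})

test_that("a 2 mm lumen at 0.6 mm spacing is still measurable", {
  ph <- tiny_tube(lumen_mm = 2, wall_mm = 1, spacing = 0.6)
  m <- measure_cross_section(ph$volume, c(0, 0, 7), c(0, 0, 1))
  expect_true(m$valid)
  expect_lt(abs(2 * sqrt(m$LA / pi) - 2), 0.3)
})

test_that("degenerate inputs are rejected", {
  ph <- tiny_tube()
  expect_error(measure_cross_section(ph$volume, c(500, 0, 7), c(0, 0, 1)),
               "outside")
  expect_error(measure_cross_section(ph$volume, c(0, 0, 7), c(0, 0, 0)),
               "tangent")
})

test_that("sections without a wall in reach are invalid with a reason", {
  # homogeneous parenchyma: no wall peak anywhere
  flat <- volume_grid(array(-850, c(30, 30, 30)), spacing = 1)
  m <- measure_cross_section(flat, c(15, 15, 15), c(0, 0, 1))
  expect_false(m$valid)
  expect_match(m$reason, "discarded")
})

test_that("branch summaries use medians of valid sections and drop short branches", {
  secs <- tibble::tibble(
    branch_id = "b", generation = 5L, lobe = "RUL", pos_mm = 1:3,
    LA = c(10, 11, 12), WA = c(5, 5, 5), TD = 1, WT = 1, WP = 1,
    valid = TRUE, reason = NA_character_, n_rays_used = 64L
  )
  s <- summarize_branch(secs)
  expect_equal(s$LA_mm2, 11)
  expect_false(s$excluded)
  one <- summarize_branch(secs[2, ])
  expect_equal(one$LA_mm2, 11)

  none <- summarize_branch(secs[0, ])
  expect_true(none$excluded)
  expect_match(none$exclusion_reason, "short")
  invalid <- secs; invalid$valid <- FALSE
  ex <- summarize_branch(invalid)
  expect_true(ex$excluded)
  expect_match(ex$exclusion_reason, "valid")

  # a branch shorter than twice the end exclusion yields no sections at all
  ph <- tiny_tube(length_mm = 3.5)
  mt <- measure_tree(ph$volume, ph$tree)
  expect_true(mt$excluded)
})

test_that("bifurcation-adjacent sections are excluded before the median", {
  ph <- tiny_tube(length_mm = 14)
  mt <- measure_tree(ph$volume, ph$tree,
                     measure_params(end_exclusion_mm = 3))
  secs <- tree_sections(mt)
  expect_true(all(secs$pos_mm >= 3 & secs$pos_mm <= 11))
})

test_that("measurement is rotation invariant within 2%", {
  base <- NULL
  for (ang in c(0, 30, 60) * pi / 180) {
    L <- 14
    spec <- airway_tree_spec(tibble::tibble(
      id = "t", parent = NA_character_,
      x0 = 0, y0 = 0, z0 = 0,
      x1 = L * sin(ang), y1 = 0, z1 = L * cos(ang),
      lumen_diameter_mm = 4, wall_thickness_mm = 1
    ))
    ph <- make_airway_phantom(spec, spacing = 0.5)
    mt <- measure_tree(ph$volume, ph$tree)
    if (is.null(base)) {
      base <- mt
    } else {
      expect_lt(abs(mt$lumen_diameter_mm / base$lumen_diameter_mm - 1), 0.02)
      expect_lt(abs(mt$TD_mm / base$TD_mm - 1), 0.02)
    }
  }
})

test_that("regional aggregation pools sections and matches a brute-force oracle", {
  spec <- six_lobe_tree_spec(max_generation = 6)
  ph <- make_airway_phantom(spec, spacing = 0.7, seed = 2)
  tree <- assign_lobes(label_generations(ph$tree), lobar_entries(spec))
  mt <- measure_tree(ph$volume, tree,
                     measure_params(plane_res_mm = 0.15, max_radius_mm = 6))
  secs <- tree_sections(mt)

  # generation range boundary: a G4 branch never enters the 5-10 aggregate
  agg <- aggregate_region(mt, c(5, 10), "total")
  used <- secs$valid & secs$generation >= 5 & secs$generation <= 10 &
    !secs$lobe %in% c("trachea", "main")
  expect_equal(agg$n_sections, sum(used))
  expect_false(any(secs$generation[used] == 4))

  # total-lung aggregate equals pooling all lobar section sets
  pooled <- secs[used, ]
  expect_equal(agg$LA_mm2, median(pooled$LA))
  expect_equal(agg$WP_pct, median(pooled$WP))
  lobar <- dplyr::bind_rows(lapply(names(lobe_labels()), function(lb) {
    aggregate_region(mt, c(5, 10), lb)
  }))
  expect_equal(sum(lobar$n_sections), agg$n_sections)
  # pooling lobar section sets reproduces the direct total median
  per_lobe_secs <- do.call(rbind, lapply(names(lobe_labels()), function(lb) {
    secs[secs$valid & secs$generation >= 5 & secs$generation <= 10 &
           secs$lobe == lb, ]
  }))
  expect_equal(median(per_lobe_secs$LA), agg$LA_mm2)

  # weighted (section-pooled) vs unweighted (branch-median) aggregation
  # differ when branch section counts are unequal
  branch_medians <- tapply(pooled$LA, pooled$branch_id, median)
  expect_false(isTRUE(all.equal(median(branch_medians), median(pooled$LA))))

  # empty selection reports missing, never zero
  empty <- aggregate_region(mt, c(9, 10), "RUL")
  expect_true(is.na(empty$LA_mm2))
  expect_equal(empty$n_sections, 0L)
})

test_that("phantom-grade airway segmentation recovers a tube lumen", {
  ph <- tiny_tube(lumen_mm = 4, wall_mm = 1, spacing = 0.5)
  seg <- segment_airways(ph$volume, c(0, 0, 7))
  vol <- sum(seg) * voxel_volume_mm3(ph$volume)
  truth <- pi * 2^2 * 14
  expect_lt(abs(vol - truth) / truth, 0.25)
})
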