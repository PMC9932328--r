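#' @keywords internal
region_selector <- function(mask, region, labels = lobe_labels()) {
  if (identical(region, "total")) {
    mask$data > 0
  } else {
    if (!region %in% names(labels)) {
      stop("unknown region: ", region, call. = FALSE)
    }
    mask$data == labels[[region]]
  }
}

#' Volume of a labelled region in cubic centimetres
#'
#' Voxel count times voxel volume; used for the total (inspiratory) and
#' residual (expiratory) lung volumes, TLV and RLV.
#'
#' @param grid a [volume_grid()] (supplies geometry; values unused).
#' @param mask an aligned label mask ([volume_grid()] of integers).
#' @param region a region name present in `labels`, or `"total"`.
#' @param labels named integer label map (default [lobe_labels()]).
#' @return volume in cm^3.
#' @export
region_volume <- function(grid, mask, region = "total", labels = lobe_labels()) {
  check_mask_alignment(grid, mask)
  sel <- region_selector(mask, region, labels)
  n <- sum(sel)
  if (n == 0) stop("region '", region, "' is empty", call. = FALSE)
  n * voxel_volume_mm3(grid) / 1000
}

#' Relative volume change of the -856 to -950 HU attenuation band
#'
#' For each scan, the relative volume of parenchyma with attenuation in
#' [-950, -856] HU is computed over the non-emphysematous lung (voxels above
#' -950 HU); the index is the expiratory minus the inspiratory relative
#' volume. It ranges from -1 to 0, with values closer to zero indicating
#' more air trapping. Band edges are inclusive so voxel counts are
#' reproducible bit-exactly.
#'
#' @param insp,exp inspiratory and expiratory [volume_grid()]s (HU).
#' @param insp_mask,exp_mask aligned label masks.
#' @param region region name or `"total"`.
#' @param band attenuation band (HU), default `c(-950, -856)`.
#' @param labels named integer label map.
#' @return RVC (dimensionless).
#' @export
compute_rvc <- function(insp, exp, insp_mask, exp_mask, region = "total",
                        band = c(-950, -856), labels = lobe_labels()) {
  check_mask_alignment(insp, insp_mask)
  check_mask_alignment(exp, exp_mask)
  band <- sort(band)
  rv <- function(grid, mask) {
    hu <- grid$data[region_selector(mask, region, labels)]
    denom <- sum(hu > band[1])
    if (denom == 0) {
      stop("no non-emphysematous voxels (all at or below ", band[1],
           " HU) in region '", region, "'", call. = FALSE)
    }
    sum(hu >= band[1] & hu <= band[2]) / denom
  }
  rv(exp, exp_mask) - rv(insp, insp_mask)
}

#' Expiratory-to-inspiratory ratio of mean lung attenuation
#'
#' Mean HU over the expiratory region divided by mean HU over the
#' inspiratory region. Both means are negative in aerated lung, so the
#' ratio lies in (0, 1]; values closer to 1 indicate more air trapping
#' (the lung fails to densify on expiration).
#'
#' @inheritParams compute_rvc
#' @return E/I MLA (dimensionless).
#' @export
compute_ei_mla <- function(insp, exp, insp_mask, exp_mask, region = "total",
                           labels = lobe_labels()) {
  check_mask_alignment(insp, insp_mask)
  check_mask_alignment(exp, exp_mask)
  mla_i <- mean(insp$data[region_selector(insp_mask, region, labels)])
  mla_e <- mean(exp$data[region_selector(exp_mask, region, labels)])
  if (mla_i == 0) stop("inspiratory mean lung attenuation is zero", call. = FALSE)
  mla_e / mla_i
}

#' Patient-specific air-trapping thresholds from the two mean attenuations
#'
#' Three nested thresholds interpolate between the inspiratory and
#' expiratory mean lung attenuation: `T_k = MLA_I + f_k * (MLA_E - MLA_I)`
#' with fractions `f1 > f2 > f3` (defaults 0.75, 0.50, 0.25), so that
#' `T1 > T2 > T3` on the HU scale. T1 yields the liberal (mild) defect
#' definition A1, T3 the stringent (severe) A3. The scheme is patient
#' specific through the two MLAs; the fractions are configurable.
#'
#' @param mla_i,mla_e inspiratory and expiratory mean lung attenuation (HU);
#'   physiology requires `mla_e > mla_i`.
#' @param fractions strictly decreasing fractions in (0, 1).
#' @return named numeric: `T1`, `T2`, `T3` (HU).
#' @examples
#' derive_at_thresholds(-850, -650)  # -700, -750, -800
#' @export
derive_at_thresholds <- function(mla_i, mla_e, fractions = c(0.75, 0.50, 0.25)) {
  if (length(fractions) != 3L || any(diff(fractions) > 0)) {
    stop("fractions must be three non-increasing values", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (mla_e <= mla_i) {
    stop("non-physiological pair: expiratory MLA must exceed inspiratory MLA",
         call. = FALSE)
  }
  stats::setNames(mla_i + fractions * (mla_e - mla_i), c("T1", "T2", "T3"))
}

#' Air-trapping defect percentages under nested thresholds
#'
#' `A_k` is the percentage of analysed expiratory parenchyma in the region
#' with attenuation at or below threshold `T_k`. Because `T1 >= T2 >= T3`,
#' the nesting `A1 >= A2 >= A3` holds by construction: every severe defect
#' voxel is also a mild one.
#'
#' @param exp expiratory [volume_grid()] (HU).
#' @param exp_mask aligned label mask.
#' @param thresholds named or positional numeric of length 3 (`T1 >= T2 >=
#'   T3`, HU), e.g. from [derive_at_thresholds()].
#' @param region region name or `"total"`.
#' @param labels named integer label map.
#' @return named numeric: `A1`, `A2`, `A3` in percent.
#' @export
compute_defects <- function(exp, exp_mask, thresholds, region = "total",
                            labels = lobe_labels()) {
  check_mask_alignment(exp, exp_mask)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 3L || any(diff(thresholds) > 0)) {
    stop("thresholds must be three non-increasing HU values (T1 >= T2 >= T3)",
         call. = FALSE)
  }
  hu <- exp$data[region_selector(exp_mask, region, labels)]
  if (length(hu) == 0) stop("region '", region, "' is empty", call. = FALSE)
  stats::setNames(
    vapply(thresholds, function(t) 100 * sum(hu <= t) / length(hu), numeric(1)),
    c("A1", "A2", "A3")
  )
}

#' All air-trapping metrics per region for one paired scan
#'
#' Computes TLV, RLV, both mean attenuations, RVC856-950, E/I MLA, the
#' patient-specific thresholds T1-T3 (from the total-lung MLAs, so they are
#' shared by all lobes of one patient) and A1-A3, for the six lobes and the
#' total lung.
#'
#' @inheritParams compute_rvc
#' @param fractions threshold fractions passed to [derive_at_thresholds()].
#' @param regions regions to report (default all lobes plus `"total"`).
#' @return tibble, one row per region, columns `region, TLV_cm3, RLV_cm3,
#'   MLA_I, MLA_E, RVC, EI_MLA, T1, T2, T3, A1, A2, A3`.
#' @export
air_trapping_table <- function(insp, exp, insp_mask, exp_mask,
                               fractions = c(0.75, 0.50, 0.25),
                               regions = c(names(lobe_labels()), "total"),
                               labels = lobe_labels()) {
  mla_i_total <- mean(insp$data[region_selector(insp_mask, "total", labels)])
  mla_e_total <- mean(exp$data[region_selector(exp_mask, "total", labels)])
  thr <- derive_at_thresholds(mla_i_total, mla_e_total, fractions)
  rows <- lapply(regions, function(rg) {
    hu_i <- insp$data[region_selector(insp_mask, rg, labels)]
    hu_e <- exp$data[region_selector(exp_mask, rg, labels)]
    a <- compute_defects(exp, exp_mask, thr, rg, labels)
    tibble::tibble(
      region = rg,
      TLV_cm3 = region_volume(insp, insp_mask, rg, labels),
      RLV_cm3 = region_volume(exp, exp_mask, rg, labels),
      MLA_I = mean(hu_i),
      MLA_E = mean(hu_e),
      RVC = compute_rvc(insp, exp, insp_mask, exp_mask, rg, labels = labels),
      EI_MLA = compute_ei_mla(insp, exp, insp_mask, exp_mask, rg, labels = labels),
      T1 = thr[["T1"]], T2 = thr[["T2"]], T3 = thr[["T3"]],
      A1 = a[["A1"]], A2 = a[["A2"]], A3 = a[["A3"]]
    )
  })
  dplyr::bind_rows(rows)
}
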