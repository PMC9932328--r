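#' Specification of a paired inspiratory/expiratory trapping phantom
#'
#' Attenuation model for a paired-scan phantom: inspiratory parenchyma is
#' drawn from one normal distribution, expiratory parenchyma from a denser
#' one (the lung densifies on expiration), and planted defect regions keep
#' near-inspiratory attenuation on the expiratory scan — which is exactly
#' the signature the air-trapping metrics quantify.
#'
#' @param defect_fraction target defect volume fraction per lobe: a single
#'   number for all lobes or a named vector by lobe (RUL, RML, RLL, LUL,
#'   LLi, LLL). Values in [0, 1].
#' @param insp_mean,insp_sd inspiratory parenchyma HU distribution.
#' @param exp_mean,exp_sd expiratory normal-parenchyma HU distribution;
#'   `exp_mean` must exceed `insp_mean`.
#' @param defect_mean,defect_sd expiratory defect HU distribution;
#'   `defect_mean` must lie below `exp_mean`.
#' @param blob_radius_mm radius of the spherical defect blobs (mm).
#' @param seed integer seed; every random draw of the generator flows from it.
#' @return an object of class `trapping_spec`.
#' @export
trapping_spec <- function(defect_fraction = 0, insp_mean = -850, insp_sd = 50,
                          exp_mean = -650, exp_sd = 50, defect_mean = -900,
                          defect_sd = 30, blob_radius_mm = 3, seed = 1L) {
  lobes <- names(lobe_labels())
  if (is.null(names(defect_fraction))) {
    if (length(defect_fraction) != 1L) {
      stop("defect_fraction must be a scalar or named by lobe", call. = FALSE)
    }
    defect_fraction <- stats::setNames(rep(defect_fraction, 6), lobes)
  } else {
    miss <- setdiff(lobes, names(defect_fraction))
    full <- stats::setNames(rep(0, 6), lobes)
    full[names(defect_fraction)] <- defect_fraction
    defect_fraction <- full
    if (length(miss) == 6L) warning("no known lobe names in defect_fraction")
  }
  if (any(defect_fraction < 0 | defect_fraction > 1)) {
    stop("defect fractions must lie in [0, 1]", call. = FALSE)
  }
  if (exp_mean <= insp_mean) {
    stop("expiratory normal mean HU must exceed inspiratory mean HU ",
         "(lung densifies on expiration)", call. = FALSE)
  }
  if (defect_mean >= exp_mean) {
    stop("defect mean HU must lie below the expiratory normal mean",
         call. = FALSE)
  }
  structure(
    list(defect_fraction = defect_fraction, insp_mean = insp_mean,
         insp_sd = insp_sd, exp_mean = exp_mean, exp_sd = exp_sd,
         defect_mean = defect_mean, defect_sd = defect_sd,
         blob_radius_mm = blob_radius_mm, seed = as.integer(seed)),
    class = "trapping_spec"
  )
}

#' Block lobe geometry: six disjoint boxes in a lattice
#'
#' A deliberately simple lobe layout — the interior of the grid minus a
#' 2-voxel border, split into a 2 (x) by 3 (z) arrangement of boxes
#' labelled RUL, RML, RLL (x-low column, top to bottom) and LUL, LLi, LLL.
#' Histogram metrics only need disjoint labelled regions, not anatomical
#' shape.
#'
#' @param shape grid dimensions in voxels.
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @return a label mask [volume_grid()].
#' @export
lobe_block_geometry <- function(shape = c(48, 48, 60), spacing = 1) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  lab <- array(0L, shape)
  border <- 2L
  xr <- seq.int(border + 1L, shape[1] - border)
  xs <- split(xr, cut(xr, 2, labels = FALSE))
  zr <- seq.int(border + 1L, shape[3] - border)
  zs <- split(zr, cut(zr, 3, labels = FALSE))
  yr <- seq.int(border + 1L, shape[2] - border)
  ll <- lobe_labels()
  plan <- list(
    RUL = list(x = xs[[1]], z = zs[[3]]), RML = list(x = xs[[1]], z = zs[[2]]),
    RLL = list(x = xs[[1]], z = zs[[1]]), LUL = list(x = xs[[2]], z = zs[[3]]),
    LLi = list(x = xs[[2]], z = zs[[2]]), LLL = list(x = xs[[2]], z = zs[[1]])
  )
  for (nm in names(plan)) {
    lab[plan[[nm]]$x, yr, plan[[nm]]$z] <- ll[[nm]]
  }
  volume_grid(lab, spacing = spacing)
}

#' Generate a paired inspiratory/expiratory lung phantom
#'
#' Inspiratory lung voxels are drawn from the inspiratory distribution and
#' expiratory voxels from the expiratory normal distribution, except inside
#' planted defect blobs: spheres of the requested radius placed by rejection
#' sampling entirely within one lobe (no blob straddles a lobe border),
#' with the final blob trimmed so the planted voxel count matches the target
#' fraction of the lobe. Voxels outside the lung are set to 0 HU.
#'
#' @param lobe_geometry a label-mask [volume_grid()] with labels from
#'   [lobe_labels()], e.g. [lobe_block_geometry()].
#' @param spec a [trapping_spec()].
#' @param max_attempts rejection-sampling budget per lobe before the target
#'   is declared unreachable with the requested blob size.
#' @return list: `insp`, `exp` ([volume_grid()]s), `mask` (the input
#'   geometry), `defect_mask` (logical array of planted voxels), and
#'   `defect_fractions` — a tibble of target and realized fraction per lobe.
#' @export
make_paired_lung_phantom <- function(lobe_geometry, spec,
                                     max_attempts = 5000L) {
  stopifnot(inherits(lobe_geometry, "volume_grid"),
            inherits(spec, "trapping_spec"))
  lab <- lobe_geometry$data
  d <- dim(lab)
  ll <- lobe_labels()
  run <- local_rng(spec$seed)
  run({
    n_lung <- sum(lab > 0)
    insp_hu <- array(0, d)
    insp_hu[lab > 0] <- stats::rnorm(n_lung, spec$insp_mean, spec$insp_sd)
    defect <- array(FALSE, d)
    frac_rows <- list()
    r_vox <- spec$blob_radius_mm / lobe_geometry$spacing
    for (lobe in names(ll)) {
      sel <- lab == ll[[lobe]]
      n_lobe <- sum(sel)
      if (n_lobe == 0) next
      target_n <- round(spec$defect_fraction[[lobe]] * n_lobe)
      planted <- 0L
      attempts <- 0L
      idx_lobe <- which(sel)
      while (planted < target_n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("defect fraction target unreachable in lobe ", lobe,
               " with blob radius ", spec$blob_radius_mm, " mm", call. = FALSE)
        }
        ctr <- arrayInd(sample(idx_lobe, 1L), d)
        ilo <- pmax(ctr - ceiling(r_vox), 1)
        ihi <- pmin(ctr + ceiling(r_vox), d)
        ii <- seq.int(ilo[1], ihi[1]); jj <- seq.int(ilo[2], ihi[2])
        kk <- seq.int(ilo[3], ihi[3])
        gx <- (rep(ii, times = length(jj) * length(kk)) - ctr[1]) / r_vox[1]
        gy <- (rep(rep(jj, each = length(ii)), times = length(kk)) - ctr[2]) / r_vox[2]
        gz <- (rep(kk, each = length(ii) * length(jj)) - ctr[3]) / r_vox[3]
        dist2 <- gx^2 + gy^2 + gz^2
        in_sph <- dist2 <= 1
        lin <- (rep(kk, each = length(ii) * length(jj)) - 1) * d[1] * d[2] +
          (rep(rep(jj, each = length(ii)), times = length(kk)) - 1) * d[1] +
          rep(ii, times = length(jj) * length(kk))
        sphere_lin <- lin[in_sph]
        # reject blobs that cross the lobe border or leave the grid
        if (any(lab[sphere_lin] != ll[[lobe]])) next
        new_vox <- sphere_lin[!defect[sphere_lin]]
        if (!length(new_vox)) next
        need <- target_n - planted
        if (length(new_vox) > need) {
          # trim the final blob from the outside in, keeping it compact
          ord <- order(dist2[in_sph][!defect[sphere_lin]])
          new_vox <- new_vox[ord][seq_len(need)]
        }
        defect[new_vox] <- TRUE
        planted <- planted + length(new_vox)
      }
      frac_rows[[lobe]] <- tibble::tibble(
        region = lobe,
        target_fraction = spec$defect_fraction[[lobe]],
        realized_fraction = planted / n_lobe,
        n_defect_voxels = planted, n_lobe_voxels = n_lobe
      )
    }
    exp_hu <- array(0, d)
    normal_e <- lab > 0 & !defect
    exp_hu[normal_e] <- stats::rnorm(sum(normal_e), spec$exp_mean, spec$exp_sd)
    exp_hu[defect] <- stats::rnorm(sum(defect), spec$defect_mean, spec$defect_sd)
    list(
      insp = volume_grid(insp_hu, lobe_geometry$spacing, lobe_geometry$origin),
      exp = volume_grid(exp_hu, lobe_geometry$spacing, lobe_geometry$origin),
      mask = lobe_geometry,
      defect_mask = defect,
      defect_fractions = dplyr::bind_rows(frac_rows)
    )
  })
}
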