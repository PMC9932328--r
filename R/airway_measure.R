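#' Measurement parameters for airway cross-sections
#'
#' Defaults: 64 rays per section, 0.25 mm in-plane sampling, 10 mm maximum
#' ray radius, 100 HU minimum lumen-to-wall contrast for a ray to count,
#' sections rejected when more than 25% of rays fail, sections sampled every
#' 1 mm along the centerline with 2 mm excluded at either end of a branch.
#'
#' @param n_rays number of rays cast from the lumen point.
#' @param plane_res_mm radial sampling step in the section plane (mm).
#' @param max_radius_mm maximum search radius along each ray (mm).
#' @param min_contrast_hu minimum wall-peak elevation above lumen HU.
#' @param max_discard_frac maximum tolerated fraction of failed rays.
#' @param section_step_mm centerline distance between sections (mm).
#' @param end_exclusion_mm centerline distance near branch endpoints within
#'   which sections are dropped (bifurcation exclusion, mm).
#' @param interp `"cubic"` (default) resamples the section plane with Keys
#'   cubic convolution, `"linear"` with trilinear interpolation. Cubic is
#'   the default because trilinear blur attenuates the wall peak of
#'   thin-walled airways and biases half-maximum borders inward.
#' @param peak_quantile quantile of the per-ray wall-peak values used as the
#'   section-level wall HU reference for the half levels. Per-ray peaks are
#'   attenuated by resampling in a grid-phase-dependent way; a high quantile
#'   across rays recovers the least-attenuated estimate of the wall HU and
#'   removes most of the inward half-maximum bias on walls at voxel scale.
#' @return a list of parameters.
#' @export
measure_params <- function(n_rays = 64L, plane_res_mm = 0.1,
                           max_radius_mm = 10, min_contrast_hu = 100,
                           max_discard_frac = 0.25, section_step_mm = 1,
                           end_exclusion_mm = 2, interp = c("cubic", "linear"),
                           peak_quantile = 0.9) {
  stopifnot(n_rays >= 8, plane_res_mm > 0, max_radius_mm > 0,
            max_discard_frac >= 0, max_discard_frac < 1)
  list(n_rays = as.integer(n_rays), plane_res_mm = plane_res_mm,
       max_radius_mm = max_radius_mm, min_contrast_hu = min_contrast_hu,
       max_discard_frac = max_discard_frac, section_step_mm = section_step_mm,
       end_exclusion_mm = end_exclusion_mm, interp = match.arg(interp),
       peak_quantile = peak_quantile)
}

# derive TD, WT, WP from lumen and wall areas (equivalent-circle convention)
section_derive <- function(LA, WA) {
  TD <- 2 * sqrt((LA + WA) / pi)
  WT <- (TD - 2 * sqrt(LA / pi)) / 2
  WP <- 100 * WA / (LA + WA)
  list(TD = TD, WT = WT, WP = WP)
}

#' Measure one airway cross-section by full-width-half-maximum ray casting
#'
#' A plane orthogonal to the centerline tangent is resampled by trilinear
#' interpolation and rays are cast outward from the lumen point. Along each
#' ray the inner wall border is the half-rise position between the lumen HU
#' and the wall peak HU, and the outer border the half-fall position between
#' the wall peak and the outer parenchyma plateau, both refined by linear
#' sub-sample interpolation. The wall HU entering the half levels is a
#' section-level reference (see `peak_quantile` in [measure_params()]); each
#' ray's own peak gates the minimum contrast and anchors the fall search. Rays that find no sufficiently contrasted peak
#' or no plateau crossing within the maximum radius are discarded; the
#' section is invalid if too many rays fail. Lumen area (LA) and the outer
#' area are the areas of the polygons through the retained border points;
#' wall area WA is their difference, and the derived quantities satisfy
#' WP = 100*WA/(LA+WA), TD = 2*sqrt((LA+WA)/pi), WT = (TD - 2*sqrt(LA/pi))/2.
#'
#' @param grid a [volume_grid()] in HU.
#' @param point numeric length 3, centerline point (mm), assumed inside the
#'   lumen.
#' @param tangent numeric length 3, centerline direction at `point`.
#' @param params a [measure_params()] list.
#' @return one-row tibble: `LA`, `WA`, `TD`, `WT`, `WP`, `valid`, `reason`,
#'   `n_rays_used`.
#' @export
measure_cross_section <- function(grid, point, tangent,
                                  params = measure_params()) {
  stopifnot(inherits(grid, "volume_grid"))
  point <- as.numeric(point); tangent <- as.numeric(tangent)
  tn <- sqrt(sum(tangent^2))
  if (!is.finite(tn) || tn == 0) stop("degenerate tangent", call. = FALSE)
  d <- dim(grid$data)
  vi <- world_to_voxel(grid, rbind(point))
  if (any(vi < 1) || any(vi > d)) stop("point outside grid", call. = FALSE)
  tangent <- tangent / tn
  # orthonormal in-plane basis
  ref <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * tangent) * tangent
  u <- u / sqrt(sum(u^2))
  w <- c(tangent[2] * u[3] - tangent[3] * u[2],
         tangent[3] * u[1] - tangent[1] * u[3],
         tangent[1] * u[2] - tangent[2] * u[1])
  nr <- params$n_rays
  theta <- 2 * pi * (seq_len(nr) - 1) / nr
  rr <- seq(0, params$max_radius_mm, by = params$plane_res_mm)
  nj <- length(rr)
  dirs <- outer(cos(theta), u) + outer(sin(theta), w)  # nr x 3
  pts <- matrix(rep(point, each = nr * nj), ncol = 3) +
    dirs[rep(seq_len(nr), each = nj), ] * rr
  interp_fun <- if (identical(params$interp, "linear")) interp_trilinear else interp_tricubic
  prof <- matrix(interp_fun(grid, pts), nrow = nj)  # nj x nr
  lumen_level <- mean(prof[1:min(2, nj), ], na.rm = TRUE)

  # section-level wall HU reference: per-ray peaks are attenuated by
  # resampling depending on where the wall falls relative to the voxel
  # lattice; the high quantile across rays is the least-attenuated estimate
  peaks <- suppressWarnings(apply(prof, 2, max, na.rm = TRUE))
  peaks[!is.finite(peaks)] <- NA_real_
  peak_ref <- stats::quantile(peaks, params$peak_quantile, na.rm = TRUE,
                              names = FALSE)
  r_in <- rep(NA_real_, nr)
  r_out <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    p <- prof[, i]
    ok <- !is.na(p)
    if (sum(ok) < 4) next
    jmax <- max(which(ok))
    p <- p[seq_len(jmax)]
    if (anyNA(p)) next
    jp <- which.max(p)
    if (jp <= 1 || jp >= length(p)) next
    if (p[jp] - lumen_level < params$min_contrast_hu) next
    half_rise <- (lumen_level + peak_ref) / 2
    cross <- which(p[seq_len(jp)] >= half_rise)
    if (!length(cross) || cross[1] <= 1) next
    j <- cross[1]
    frac <- (half_rise - p[j - 1]) / (p[j] - p[j - 1])
    r_in[i] <- rr[j - 1] + frac * (rr[j] - rr[j - 1])
    after <- p[jp:length(p)]
    plateau <- min(after)
    half_fall <- (peak_ref + plateau) / 2
    crossf <- which(after <= half_fall)
    if (!length(crossf)) next
    if (crossf[1] == 1) {
      # this ray's local peak already sits below the half-fall level; the
      # outer border collapses onto the peak position
      r_out[i] <- rr[jp]
    } else {
      jf <- jp + crossf[1] - 1
      fracf <- (half_fall - p[jf - 1]) / (p[jf] - p[jf - 1])
      r_out[i] <- rr[jf - 1] + fracf * (rr[jf] - rr[jf - 1])
    }
  }
  used <- !is.na(r_in) & !is.na(r_out) & r_out > r_in
  fail_frac <- 1 - sum(used) / nr
  invalid_row <- function(reason) tibble::tibble(
    LA = NA_real_, WA = NA_real_, TD = NA_real_, WT = NA_real_,
    WP = NA_real_, valid = FALSE, reason = reason, n_rays_used = sum(used)
  )
  if (fail_frac > params$max_discard_frac) {
    return(invalid_row(sprintf("%.0f%% of rays discarded", 100 * fail_frac)))
  }
  th <- theta[used]
  polygon_area <- function(r) {
    k <- length(r)
    nxt <- c(2:k, 1)
    dth <- (th[nxt] - th) %% (2 * pi)
    0.5 * sum(r * r[nxt] * sin(dth))
  }
  LA <- polygon_area(r_in[used])
  outer_area <- polygon_area(r_out[used])
  WA <- outer_area - LA
  if (!is.finite(LA) || LA <= 0 || WA <= 0) {
    return(invalid_row("non-positive lumen or wall area"))
  }
  drv <- section_derive(LA, WA)
  tibble::tibble(LA = LA, WA = WA, TD = drv$TD, WT = drv$WT, WP = drv$WP,
                 valid = TRUE, reason = NA_character_, n_rays_used = sum(used))
}

# arclength-parameterized point/tangent along a polyline centerline
centerline_samples <- function(cl, step, exclusion) {
  seg <- diff(cl)
  seg_len <- sqrt(rowSums(seg^2))
  L <- sum(seg_len)
  if (L <= 2 * exclusion) return(NULL)
  s <- seq(exclusion, L - exclusion, by = step)
  cum <- c(0, cumsum(seg_len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(cl)] <- nrow(cl) - 1L
  frac <- (s - cum[idx]) / seg_len[idx]
  pts <- cl[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tan <- seg[idx, , drop = FALSE] / seg_len[idx]
  list(s = s, points = pts, tangents = tan)
}

#' Summarize measured sections into per-branch geometry
#'
#' Per-branch TD/WT/LA/WP are medians over the valid sections; sections
#' within the bifurcation-exclusion distance of either branch endpoint have
#' already been dropped at sampling time. Branches without a single valid
#' section are excluded with a reason code.
#'
#' @param sections tibble of per-section measures for one branch (as emitted
#'   by [measure_tree()]).
#' @return one-row tibble of branch geometry with `n_sections_valid` and
#'   `excluded`/`exclusion_reason`.
#' @export
summarize_branch <- function(sections) {
  val <- sections[sections$valid %in% TRUE, , drop = FALSE]
  if (nrow(val) == 0) {
    return(tibble::tibble(
      LA_mm2 = NA_real_, WA_mm2 = NA_real_, TD_mm = NA_real_, WT_mm = NA_real_,
      WP_pct = NA_real_, lumen_diameter_mm = NA_real_,
      n_sections_valid = 0L, excluded = TRUE,
      exclusion_reason = if (nrow(sections) == 0) "no sections (branch too short)"
      else "no valid sections"
    ))
  }
  LA <- stats::median(val$LA)
  tibble::tibble(
    LA_mm2 = LA,
    WA_mm2 = stats::median(val$WA),
    TD_mm = stats::median(val$TD),
    WT_mm = stats::median(val$WT),
    WP_pct = stats::median(val$WP),
    lumen_diameter_mm = 2 * sqrt(LA / pi),
    n_sections_valid = nrow(val),
    excluded = FALSE,
    exclusion_reason = NA_character_
  )
}

#' Measure airway geometry over a whole tree
#'
#' Samples cross-sections along every branch centerline (default every 1 mm,
#' excluding 2 mm near each endpoint), measures each with
#' [measure_cross_section()], and attaches per-branch median geometry to the
#' tree. Any ground-truth `lumen_diameter_mm`/`wall_thickness_mm` columns
#' are preserved under a `_true` suffix.
#'
#' @param grid a [volume_grid()] in HU.
#' @param tree an [airway_tree()]; generations are labelled if absent.
#' @param params a [measure_params()] list.
#' @return the tree with measured geometry columns; the full per-section
#'   table (one row per sampled section) is attached as attribute
#'   `"sections"` and via [tree_sections()].
#' @export
measure_tree <- function(grid, tree, params = measure_params()) {
  stopifnot(inherits(tree, "airway_tree"))
  if (!"generation" %in% names(tree)) tree <- label_generations(tree)
  if (!"lobe" %in% names(tree)) tree$lobe <- NA_character_
  sec_list <- vector("list", nrow(tree))
  geo_list <- vector("list", nrow(tree))
  for (i in seq_len(nrow(tree))) {
    cs <- centerline_samples(tree$centerline[[i]], params$section_step_mm,
                             params$end_exclusion_mm)
    if (is.null(cs)) {
      secs <- tibble::tibble(
        branch_id = character(), generation = integer(), lobe = character(),
        pos_mm = numeric(), LA = numeric(), WA = numeric(), TD = numeric(),
        WT = numeric(), WP = numeric(), valid = logical(), reason = character(),
        n_rays_used = integer()
      )
    } else {
      rows <- lapply(seq_along(cs$s), function(k) {
        measure_cross_section(grid, cs$points[k, ], cs$tangents[k, ], params)
      })
      secs <- dplyr::bind_rows(rows)
      secs <- dplyr::mutate(
        secs,
        branch_id = tree$id[i], generation = tree$generation[i],
        lobe = tree$lobe[i], pos_mm = cs$s,
        .before = 1
      )
    }
    sec_list[[i]] <- secs
    geo_list[[i]] <- summarize_branch(secs)
  }
  geo <- dplyr::bind_rows(geo_list)
  out <- tree
  if ("lumen_diameter_mm" %in% names(out)) {
    out$lumen_diameter_true_mm <- out$lumen_diameter_mm
    out$lumen_diameter_mm <- NULL
  }
  if ("wall_thickness_mm" %in% names(out)) {
    out$wall_thickness_true_mm <- out$wall_thickness_mm
    out$wall_thickness_mm <- NULL
  }
  out <- dplyr::bind_cols(out, geo)
  attr(out, "sections") <- dplyr::bind_rows(sec_list)
  attr(out, "measured") <- TRUE
  out
}

#' Per-section measurement table of a measured tree
#'
#' @param tree output of [measure_tree()].
#' @return tibble with one row per sampled cross-section.
#' @export
tree_sections <- function(tree) {
  s <- attr(tree, "sections")
  if (is.null(s)) stop("tree has no section table; run measure_tree() first",
                       call. = FALSE)
  s
}

#' Aggregate airway geometry over a generation range and region
#'
#' The aggregate is the median over all valid cross-sections of branches
#' whose generation lies in `generations` and whose lobe equals `region`
#' (every lobe for the total lung), so branches contribute in proportion to
#' their section counts. An empty selection yields missing aggregates,
#' never zeros.
#'
#' @param tree a measured tree from [measure_tree()].
#' @param generations integer length 2, inclusive generation range
#'   (default c(5, 10), the subsegmental aggregation window).
#' @param region a lobe name, or `"total"` for the whole lung.
#' @return one-row tibble: region, generation range, `TD_mm`, `WT_mm`,
#'   `LA_mm2`, `WP_pct`, `n_sections`, `n_branches`.
#' @export
aggregate_region <- function(tree, generations = c(5, 10), region = "total") {
  secs <- tree_sections(tree)
  sel <- secs$valid %in% TRUE &
    secs$generation >= generations[1] & secs$generation <= generations[2]
  if (!identical(region, "total")) {
    sel <- sel & !is.na(secs$lobe) & secs$lobe == region
  } else {
    sel <- sel & !is.na(secs$lobe) &
      !(secs$lobe %in% c("trachea", "main", "unassigned"))
  }
  secs <- secs[sel, , drop = FALSE]
  if (nrow(secs) == 0) {
    return(tibble::tibble(
      region = region, gen_lo = generations[1], gen_hi = generations[2],
      TD_mm = NA_real_, WT_mm = NA_real_, LA_mm2 = NA_real_, WP_pct = NA_real_,
      n_sections = 0L, n_branches = 0L
    ))
  }
  tibble::tibble(
    region = region, gen_lo = generations[1], gen_hi = generations[2],
    TD_mm = stats::median(secs$TD), WT_mm = stats::median(secs$WT),
    LA_mm2 = stats::median(secs$LA), WP_pct = stats::median(secs$WP),
    n_sections = nrow(secs), n_branches = length(unique(secs$branch_id))
  )
}

#' Bronchiectasis index from airway tapering violations
#'
#' In a healthy airway tree the lumen narrows with every generation. For
#' every measured parent-child branch pair (child generation >= 3) the
#' tapering error is the normalized positive excess of the child lumen
#' diameter over `kappa` times the parent's:
#' `e = max(0, (LD_child - kappa * LD_parent) / LD_parent)`. The
#' bronchiectasis index of a region is the sum of these errors over pairs
#' whose child lies in the region; a strictly tapering tree scores exactly
#' 0 and each independent dilation adds its own error, so lobar values sum.
#'
#' @param tree an [airway_tree()] carrying `lumen_diameter_mm` per branch —
#'   either measured ([measure_tree()]) or exact phantom truth.
#' @param region a lobe name or `"total"`.
#' @param kappa tapering-reserve factor; 1 means any child wider than its
#'   parent counts.
#' @param min_child_generation pairs with a shallower child are skipped
#'   (default 3: lobar and deeper).
#' @return one-row tibble: `region`, `BEI`, `n_pairs`.
#' @export
compute_bei <- function(tree, region = "total", kappa = 1,
                        min_child_generation = 3L) {
  stopifnot(inherits(tree, "airway_tree"))
  if (!"lumen_diameter_mm" %in% names(tree)) {
    stop("tree carries no lumen diameters; measure it or use phantom truth",
         call. = FALSE)
  }
  if (!"generation" %in% names(tree)) tree <- label_generations(tree)
  ld <- stats::setNames(tree$lumen_diameter_mm, tree$id)
  lobe <- if (!"lobe" %in% names(tree)) stats::setNames(rep(NA_character_, nrow(tree)), tree$id)
  else stats::setNames(tree$lobe, tree$id)
  kids <- tree[!is.na(tree$parent), , drop = FALSE]
  keep <- kids$generation >= min_child_generation &
    !is.na(ld[kids$id]) & !is.na(ld[kids$parent])
  if (!identical(region, "total")) {
    keep <- keep & !is.na(lobe[kids$id]) & lobe[kids$id] == region
  }
  kids <- kids[keep, , drop = FALSE]
  err <- pmax(0, (ld[kids$id] - kappa * ld[kids$parent]) / ld[kids$parent])
  tibble::tibble(region = region, BEI = sum(err), n_pairs = nrow(kids))
}

#' Phantom-grade airway segmentation by threshold region growing
#'
#' Grows a 6-connected region from a seed voxel over voxels below an HU
#' threshold, with a simple wavefront leak guard: growth stops if a
#' wavefront suddenly exceeds `leak_factor` times the running median
#' wavefront size. Adequate for digital phantoms; clinical-grade airway
#' segmentation is out of scope.
#'
#' @param grid a [volume_grid()] in HU.
#' @param seed_point physical seed coordinate (mm) inside the lumen.
#' @param threshold_hu voxels strictly below this HU are airway candidates.
#' @param leak_factor wavefront growth ratio that triggers the leak guard.
#' @return logical array of the segmented lumen, same shape as the volume.
#' @export
segment_airways <- function(grid, seed_point, threshold_hu = -925,
                            leak_factor = 4) {
  d <- dim(grid$data)
  seed <- round(world_to_voxel(grid, rbind(seed_point)))
  if (any(seed < 1) || any(seed > d)) stop("seed outside grid", call. = FALSE)
  cand <- grid$data < threshold_hu
  if (!cand[seed[1], seed[2], seed[3]]) {
    stop("seed voxel is not below the airway threshold", call. = FALSE)
  }
  lin <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  visited <- logical(prod(d))
  front <- lin(seed[1], seed[2], seed[3])
  visited[front] <- TRUE
  sizes <- integer(0)
  offs <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  cand_v <- as.vector(cand)
  # precompute face masks to stop 6-neighbourhood wrap-around at edges
  ii <- arrayInd(seq_len(prod(d)), d)
  ok_off <- list(ii[, 1] > 1, ii[, 1] < d[1], ii[, 2] > 1, ii[, 2] < d[2],
                 ii[, 3] > 1, ii[, 3] < d[3])
  while (length(front)) {
    nbrs <- unlist(lapply(seq_along(offs), function(m) {
      f <- front[ok_off[[m]][front]]
      f + offs[m]
    }))
    nbrs <- unique(nbrs[cand_v[nbrs] & !visited[nbrs]])
    if (length(sizes) >= 3 &&
        length(nbrs) > leak_factor * stats::median(utils::tail(sizes, 10))) {
      warning("wavefront leak detected; region growing stopped", call. = FALSE)
      break
    }
    visited[nbrs] <- TRUE
    sizes <- c(sizes, length(nbrs))
    front <- nbrs
  }
  array(visited, d)
}
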