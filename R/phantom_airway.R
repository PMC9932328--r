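#' Specification of a synthetic airway tree phantom
#'
#' Describes a set of straight tubular branches (air-filled lumen surrounded
#' by a soft-tissue wall annulus, embedded in parenchyma-like background)
#' together with the attenuation values of the three materials. Typical HU:
#' lumen air -1000, wall soft tissue 0, parenchyma around -850.
#'
#' @param branches data frame with columns `id`, `parent` (`NA` for the
#'   trachea), `x0, y0, z0, x1, y1, z1` (start/end of the branch axis, mm),
#'   `lumen_diameter_mm` (> 0), `wall_thickness_mm` (> 0) and optionally
#'   `lobe`.
#' @param lumen_hu,wall_hu,background_hu attenuation of lumen, wall and
#'   background material (HU).
#' @return an object of class `airway_tree_spec`.
#' @export
airway_tree_spec <- function(branches, lumen_hu = -1000, wall_hu = 0,
                             background_hu = -850) {
  branches <- tibble::as_tibble(branches)
  req <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1",
           "lumen_diameter_mm", "wall_thickness_mm")
  miss <- setdiff(req, names(branches))
  if (length(miss)) {
    stop("branch table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(branches$lumen_diameter_mm <= 0)) {
    stop("lumen_diameter_mm must be > 0", call. = FALSE)
  }
  if (any(branches$wall_thickness_mm <= 0)) {
    stop("wall_thickness_mm must be > 0", call. = FALSE)
  }
  if (!"lobe" %in% names(branches)) branches$lobe <- NA_character_
  spec <- structure(
    list(branches = branches, lumen_hu = lumen_hu, wall_hu = wall_hu,
         background_hu = background_hu),
    class = "airway_tree_spec"
  )
  # generation numbering is implied by topology; compute it now so the
  # invariants (single root, child = parent + 1) are checked early
  spec$branches$generation <- label_generations(spec_to_tree(spec))$generation
  spec
}

#' Ground-truth tree model implied by a phantom spec
#'
#' @param spec an [airway_tree_spec()].
#' @return an [airway_tree()] whose centerlines are the branch axes and whose
#'   `lumen_diameter_mm` / `wall_thickness_mm` columns are exact.
#' @export
spec_to_tree <- function(spec) {
  b <- spec$branches
  airway_tree(tibble::tibble(
    id = b$id,
    parent = b$parent,
    centerline = lapply(seq_len(nrow(b)), function(i) {
      rbind(c(b$x0[i], b$y0[i], b$z0[i]), c(b$x1[i], b$y1[i], b$z1[i]))
    }),
    lobe = b$lobe,
    lumen_diameter_mm = b$lumen_diameter_mm,
    wall_thickness_mm = b$wall_thickness_mm
  ))
}

#' Rasterize an airway tree spec into a CT-like volume
#'
#' Each branch becomes a cylindrical tube: air lumen, dense wall annulus,
#' parenchyma background. Voxels are rasterized with partial-volume
#' averaging: every voxel is split into 3 x 3 x 3 subsamples and its HU is
#' the mean of the material HU at the subsample points, so material
#' interfaces produce the graded edges on which half-maximum edge detection
#' is meaningful. Lumen takes precedence over wall where tubes meet.
#' Gaussian noise with standard deviation `noise_sd` HU is added when
#' `noise_sd > 0`; all randomness derives from `seed`.
#'
#' @param spec an [airway_tree_spec()].
#' @param spacing voxel spacing in mm (scalar for isotropic, or length 3).
#' @param noise_sd additive Gaussian noise sd in HU (0 = noise free).
#' @param margin_mm parenchyma margin added around the tree bounding box.
#' @param shape optional explicit grid dimensions; the default sizes the
#'   grid to fit all tubes plus `margin_mm`.
#' @param origin optional explicit grid origin (mm); required with `shape`.
#' @param seed integer seed used for the noise stream.
#' @return list with `volume` (a [volume_grid()]) and `tree` (the exact
#'   ground-truth [airway_tree()]).
#' @examples
#' spec <- straight_tube_spec(lumen_mm = 4, wall_mm = 1, length_mm = 12)
#' ph <- make_airway_phantom(spec, spacing = 0.5)
#' range(ph$volume$data)
#' @export
make_airway_phantom <- function(spec, spacing, noise_sd = 0, margin_mm = 4,
                                shape = NULL, origin = NULL, seed = 1L) {
  stopifnot(inherits(spec, "airway_tree_spec"))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive and finite (mm per voxel)", call. = FALSE)
  }
  b <- spec$branches
  r_out <- b$lumen_diameter_mm / 2 + b$wall_thickness_mm
  p0 <- cbind(b$x0, b$y0, b$z0)
  p1 <- cbind(b$x1, b$y1, b$z1)
  lo <- apply(pmin(p0, p1) - r_out, 2, min)
  hi <- apply(pmax(p0, p1) + r_out, 2, max)
  if (is.null(shape)) {
    origin <- lo - margin_mm
    shape <- ceiling((hi + margin_mm - origin) / spacing) + 1L
  } else {
    if (is.null(origin)) stop("origin must be given with an explicit shape", call. = FALSE)
    extent_hi <- origin + (shape - 1) * spacing
    if (any(lo < origin + 2 * spacing) || any(hi > extent_hi - 2 * spacing)) {
      stop("branch tube extends outside the requested grid ",
           "(need >= 2 voxels margin)", call. = FALSE)
    }
  }
  shape <- as.integer(shape)
  nsub <- shape * 3L
  n_subvox <- prod(nsub)
  in_lumen <- raw(n_subvox)
  in_outer <- raw(n_subvox)
  # subsample lattice: regular grid, spacing/3, first point at origin - spacing/3
  sub_sp <- spacing / 3
  sub_org <- origin - spacing / 3
  for (i in seq_len(nrow(b))) {
    a0 <- p0[i, ]; a1 <- p1[i, ]
    v <- a1 - a0
    len2 <- sum(v^2)
    if (len2 == 0) stop("zero-length branch: ", b$id[i], call. = FALSE)
    rl <- b$lumen_diameter_mm[i] / 2
    ro <- r_out[i]
    blo <- pmax(floor((pmin(a0, a1) - ro - sub_org) / sub_sp) + 1, 1)
    bhi <- pmin(ceiling((pmax(a0, a1) + ro - sub_org) / sub_sp) + 1, nsub)
    ix <- seq.int(blo[1], bhi[1]); iy <- seq.int(blo[2], bhi[2]); iz <- seq.int(blo[3], bhi[3])
    xs <- sub_org[1] + (ix - 1) * sub_sp[1] - a0[1]
    ys <- sub_org[2] + (iy - 1) * sub_sp[2] - a0[2]
    zs <- sub_org[3] + (iz - 1) * sub_sp[3] - a0[3]
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    # t = projection parameter onto the axis, clamped to the segment
    tx <- xs * v[1]; ty <- ys * v[2]; tz <- zs * v[3]
    tt <- (rep(tx, times = ny * nz) +
             rep(rep(ty, each = nx), times = nz) +
             rep(tz, each = nx * ny)) / len2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    dx <- rep(xs, times = ny * nz) - tt * v[1]
    dy <- rep(rep(ys, each = nx), times = nz) - tt * v[2]
    dz <- rep(zs, each = nx * ny) - tt * v[3]
    d2 <- dx * dx + dy * dy + dz * dz
    lin <- (rep(ix, times = ny * nz) - 1) +
      (rep(rep(iy, each = nx), times = nz) - 1) * nsub[1] +
      (rep(iz, each = nx * ny) - 1) * (nsub[1] * nsub[2]) + 1
    in_lumen[lin[d2 <= rl * rl]] <- as.raw(1)
    in_outer[lin[d2 <= ro * ro]] <- as.raw(1)
  }
  lum <- as.integer(in_lumen)
  out <- as.integer(in_outer)
  lum_cnt <- block_sum3(array(lum, nsub))
  out_cnt <- block_sum3(array(out, nsub))
  wall_cnt <- out_cnt - lum_cnt
  hu <- (spec$lumen_hu * lum_cnt + spec$wall_hu * wall_cnt +
           spec$background_hu * (27 - out_cnt)) / 27
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    hu <- hu + array(rng(stats::rnorm(length(hu), 0, noise_sd)), dim(hu))
  }
  vol <- volume_grid(hu, spacing = spacing, origin = origin)
  truth <- spec_to_tree(spec)
  truth$generation <- spec$branches$generation
  list(volume = vol, tree = truth)
}

# Sum an array over non-overlapping 3x3x3 blocks (dims must be multiples of
# 3); strided slice sums avoid the cost of aperm on large arrays.
block_sum3 <- function(A) {
  d <- dim(A)
  n <- d %/% 3L
  dim(A) <- c(3L, length(A) %/% 3L)
  A <- colSums(A)
  dim(A) <- c(n[1], 3L, n[2] * d[3])
  A <- A[, 1, ] + A[, 2, ] + A[, 3, ]
  dim(A) <- c(n[1] * n[2], 3L, n[3])
  A <- A[, 1, ] + A[, 2, ] + A[, 3, ]
  dim(A) <- n
  A
}

# Evaluate `expr` under a private RNG state seeded with `seed`, leaving the
# session RNG untouched: all phantom randomness flows from explicit seeds.
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
    expr
  }
}

#' Convenience phantom specs
#'
#' `straight_tube_spec()` builds a single straight airway along the z axis.
#' `tapering_chain_spec()` builds a linear chain of `n` colinear branches
#' whose lumen shrinks by `taper` at each step. `six_lobe_tree_spec()`
#' builds a compact six-lobe tree: trachea (generation 1), two main stem
#' bronchi (2), six lobar entries (3: RUL, RML, RLL, LUL, LLi, LLL), each
#' continued by a chain of subsegmental branches tapering by `taper` per
#' generation down to `max_generation`. Selected branches can be dilated to
#' a chosen ratio of their parent lumen to plant bronchiectasis with known
#' tapering-violation size.
#'
#' @param lumen_mm,wall_mm lumen diameter and wall thickness (mm).
#' @param length_mm tube length (mm).
#' @param lumen_hu,wall_hu,background_hu material HU passed through to
#'   [airway_tree_spec()].
#' @return an [airway_tree_spec()].
#' @export
straight_tube_spec <- function(lumen_mm = 4, wall_mm = 1, length_mm = 20,
                               lumen_hu = -1000, wall_hu = 0,
                               background_hu = -850) {
  airway_tree_spec(
    tibble::tibble(
      id = "t1", parent = NA_character_,
      x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = length_mm,
      lumen_diameter_mm = lumen_mm, wall_thickness_mm = wall_mm
    ),
    lumen_hu = lumen_hu, wall_hu = wall_hu, background_hu = background_hu
  )
}

#' @rdname straight_tube_spec
#' @param n number of chained branches.
#' @param taper child-to-parent lumen diameter ratio (< 1 tapers).
#' @param root_lumen_mm lumen diameter of the first branch (mm).
#' @export
tapering_chain_spec <- function(n = 6, root_lumen_mm = 6, taper = 0.8,
                                wall_mm = 1, length_mm = 10, ...) {
  lum <- root_lumen_mm * taper^(seq_len(n) - 1)
  airway_tree_spec(
    tibble::tibble(
      id = paste0("b", seq_len(n)),
      parent = c(NA_character_, paste0("b", seq_len(n - 1))),
      x0 = 0, y0 = 0, z0 = (seq_len(n) - 1) * length_mm,
      x1 = 0, y1 = 0, z1 = seq_len(n) * length_mm,
      lumen_diameter_mm = lum,
      wall_thickness_mm = wall_mm
    ),
    ...
  )
}

#' @rdname straight_tube_spec
#' @param root_lumen_mm trachea lumen diameter (mm).
#' @param max_generation deepest generation generated in each lobar chain.
#' @param dilations optional data frame with columns `lobe`, `generation`,
#'   `ratio`: the branch of that generation in that lobe has its lumen set
#'   to `ratio` times its parent's lumen (ratio > 1 plants a tapering
#'   violation of size `ratio - 1`).
#' @param branch_length_mm length of each post-lobar branch (mm).
#' @param entry_length_mm length of the lobar entry (generation 3) branches,
#'   longer than deeper branches so that most of their cross-sections clear
#'   the trifurcation neighbourhood.
#' @export
six_lobe_tree_spec <- function(root_lumen_mm = 7, taper = 0.8, wall_mm = 0.9,
                               max_generation = 6, dilations = NULL,
                               branch_length_mm = 8, entry_length_mm = 12, ...) {
  # lobar chain directions spread widely in 3D so sibling tubes separate
  # quickly beyond the shared trifurcation point
  dirs <- list(
    RUL = c(0.55, 0.45, 0.65), RML = c(0.85, -0.45, -0.28),
    RLL = c(0.40, 0.25, -0.88), LUL = c(-0.55, -0.45, 0.65),
    LLi = c(-0.85, 0.45, -0.28), LLL = c(-0.40, -0.25, -0.88)
  )
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)
  trachea_len <- 12
  add(id = "trachea", parent = NA_character_, x0 = 0, y0 = 0, z0 = 0,
      x1 = 0, y1 = 0, z1 = -trachea_len,
      lumen_diameter_mm = root_lumen_mm, wall_thickness_mm = wall_mm,
      lobe = NA_character_)
  main_lum <- root_lumen_mm * taper
  for (side in c("R", "L")) {
    sgn <- if (side == "R") 1 else -1
    add(id = paste0(side, "main"), parent = "trachea",
        x0 = 0, y0 = 0, z0 = -trachea_len,
        x1 = sgn * 8, y1 = 0, z1 = -trachea_len - 5,
        lumen_diameter_mm = main_lum, wall_thickness_mm = wall_mm,
        lobe = NA_character_)
  }
  for (lb in names(dirs)) {
    side <- if (lb %in% c("RUL", "RML", "RLL")) "R" else "L"
    sgn <- if (side == "R") 1 else -1
    pos <- c(sgn * 8, 0, -trachea_len - 5)
    dir0 <- dirs[[lb]] / sqrt(sum(dirs[[lb]]^2))
    lum <- main_lum * taper
    prev_id <- paste0(side, "main")
    for (g in 3:max_generation) {
      id <- paste0(lb, "_g", g)
      # small deterministic bend per generation keeps junctions visible
      # without letting chains re-converge
      bend <- 0.12 * (g - 3) * c(dir0[2], -dir0[1], 0)
      seg_dir <- dir0 + bend
      seg_dir <- seg_dir / sqrt(sum(seg_dir^2))
      len <- if (g == 3) entry_length_mm else branch_length_mm
      nxt <- pos + seg_dir * len
      if (!is.null(dilations)) {
        hit <- dilations$lobe == lb & dilations$generation == g
        if (any(hit)) lum <- (lum / taper) * dilations$ratio[which(hit)[1]]
      }
      add(id = id, parent = prev_id,
          x0 = pos[1], y0 = pos[2], z0 = pos[3],
          x1 = nxt[1], y1 = nxt[2], z1 = nxt[3],
          lumen_diameter_mm = lum, wall_thickness_mm = wall_mm,
          lobe = lb)
      prev_id <- id
      pos <- nxt
      lum <- lum * taper
    }
  }
  airway_tree_spec(dplyr::bind_rows(rows), ...)
}

#' Lobar entry labels implied by a six-lobe spec
#'
#' @param spec a spec built by [six_lobe_tree_spec()].
#' @return named character vector suitable for [assign_lobes()].
#' @export
lobar_entries <- function(spec) {
  b <- spec$branches
  ent <- b[!is.na(b$lobe) & b$generation == 3L, ]
  stats::setNames(ent$lobe, ent$id)
}
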