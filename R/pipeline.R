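#' Default pipeline configuration
#'
#' A nested list describing a full phantom-cohort run: phantom geometry and
#' attenuation, measurement parameters, air-trapping threshold fractions,
#' cohort design, and model requests. Every tolerance and threshold
#' defaults to the package-wide values documented in the respective
#' functions. The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param n_subjects subjects in the demo cohort.
#' @param timepoints visit months.
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(n_subjects = 8, timepoints = c(0, 3, 12, 24)) {
  cfg <- list(
    stages = c("phantom", "measure", "trap", "stats"),
    seed = 1L,
    cohort = list(n_subjects = n_subjects, timepoints = timepoints),
    airway_phantom = list(
      spacing_mm = 0.7, noise_sd_hu = 15,
      root_lumen_mm = 7, taper = 0.8, wall_mm = 0.9, max_generation = 6,
      dilation_prob = 0.4, dilation_ratio_range = c(1.2, 1.6),
      # airway calibre grows with the lung over the two study years; the
      # bronchiectasis index, a ratio measure, is unaffected by uniform growth
      growth_rate_per_year = 0.04
    ),
    lung_phantom = list(
      shape = c(48, 48, 60), spacing_mm = 1,
      insp_mean = -850, insp_sd = 50, exp_mean = -650, exp_sd = 50,
      defect_mean = -900, defect_sd = 30, blob_radius_mm = 3,
      subject_defect_range = c(0.01, 0.12), visit_defect_sd = 0.02
    ),
    measurement = list(
      n_rays = 64, plane_res_mm = 0.15, max_radius_mm = 6,
      section_step_mm = 1, end_exclusion_mm = 2, bei_kappa = 1
    ),
    trapping = list(fractions = c(0.75, 0.50, 0.25)),
    qc = list(volume_change_threshold = 0.05),
    stats = list(
      crosssectional_endpoints = c("BEI", "LA_5_10", "WP_5_10"),
      longitudinal_endpoint = "BEI",
      longitudinal_intervals = list(c(0, 3), c(0, 24)),
      robust = TRUE
    ),
    write_volumes = FALSE
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Validate a run configuration
#'
#' Checks stage names, threshold-fraction ordering, positive spacings and
#' probability bounds before any compute happens.
#'
#' @param cfg a configuration list.
#' @return invisibly, the validated config (class `run_config`).
#' @export
validate_run_config <- function(cfg) {
  known <- c("phantom", "measure", "trap", "stats")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  fr <- cfg$trapping$fractions
  if (length(fr) != 3L || any(diff(fr) >= 0)) {
    stop("trapping fractions must be three strictly decreasing values",
         call. = FALSE)
  }
  if (any(fr <= 0 | fr >= 1)) {
    stop("trapping fractions must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$airway_phantom$spacing_mm <= 0 || cfg$lung_phantom$spacing_mm <= 0) {
    stop("voxel spacings must be positive", call. = FALSE)
  }
  p <- cfg$airway_phantom$dilation_prob
  if (p < 0 || p > 1) stop("dilation_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$cohort$n_subjects < 1) stop("need at least one subject", call. = FALSE)
  if (length(cfg$cohort$timepoints) < 2) {
    stop("need at least two timepoints", call. = FALSE)
  }
  if (cfg$qc$volume_change_threshold <= 0) {
    stop("QC volume-change threshold must be positive", call. = FALSE)
  }
  if ("stats" %in% cfg$stages) {
    for (iv in cfg$stats$longitudinal_intervals) {
      if (!all(iv %in% cfg$cohort$timepoints)) {
        stop("longitudinal interval (", paste(iv, collapse = ", "),
             ") not covered by the visit schedule", call. = FALSE)
      }
    }
  }
  class(cfg) <- c("run_config", "list")
  invisible(cfg)
}

#' @rdname default_run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml scalarizes length-1 vectors; restore list-of-pairs for intervals
  if (!is.null(cfg$stats$longitudinal_intervals)) {
    cfg$stats$longitudinal_intervals <-
      lapply(cfg$stats$longitudinal_intervals, unlist)
  }
  validate_run_config(cfg)
}

# deterministic per-subject/visit seed derived from the run seed
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed)
  for (k in ids) s <- (s * 69069 + as.double(k)) %% 2147483647
  as.integer(max(1, s))
}

#' Run the phantom-cohort pipeline
#'
#' Executes the requested stages in dependency order on a synthetic cohort:
#' `phantom` generates one six-lobe airway phantom and one paired
#' inspiratory/expiratory lung phantom per subject and visit (with
#' subject-specific planted bronchiectasis and trapping severity);
#' `measure` runs the cross-section measurement, regional aggregation and
#' bronchiectasis index; `trap` computes the air-trapping table; `stats`
#' assembles the cohort table, descriptive summaries, the breath-hold QC
#' report and the cross-sectional and longitudinal mixed models. Outputs
#' are CSV/JSON files under `out_dir` plus a manifest with the
#' configuration, seed, package version and MD5 of every output; a re-run
#' with the same config and seed reproduces all outputs bit-identically.
#'
#' @param cfg a [default_run_config()]-style configuration.
#' @param out_dir output directory (created if needed).
#' @param seed integer run seed; overrides `cfg$seed` when given.
#' @return invisibly, a list with the cohort tibble, model fits, QC report
#'   and the manifest.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir, seed = NULL) {
  cfg <- validate_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("phantoms", "measures", "trapping", "stats", "qc")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stages <- cfg$stages
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages) {
      stop("stage '", stage, "' requires stage '", dep, "'", call. = FALSE)
    }
  }
  need("measure", "phantom"); need("trap", "phantom")
  need("stats", "measure"); need("stats", "trap")

  subjects <- sprintf("P%02d", seq_len(cfg$cohort$n_subjects))
  visits <- cfg$cohort$timepoints
  ap <- cfg$airway_phantom; lp <- cfg$lung_phantom
  mp <- measure_params(
    n_rays = ap_num(cfg$measurement$n_rays),
    plane_res_mm = cfg$measurement$plane_res_mm,
    max_radius_mm = cfg$measurement$max_radius_mm,
    section_step_mm = cfg$measurement$section_step_mm,
    end_exclusion_mm = cfg$measurement$end_exclusion_mm
  )
  geo <- lobe_block_geometry(shape = unlist(lp$shape), spacing = lp$spacing_mm)
  lobes <- names(lobe_labels())

  cohort_rows <- list()
  trap_rows <- list()
  qc_rows <- list()
  truth_rows <- list()
  base_age <- local_rng(derive_seed(cfg$seed, 1))(
    stats::runif(length(subjects), 8, 16)
  )

  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    srng <- local_rng(derive_seed(cfg$seed, 2, si))
    subj_draw <- srng({
      list(
        dilate = stats::runif(6) < ap$dilation_prob,
        ratio = stats::runif(6, ap$dilation_ratio_range[1],
                             ap$dilation_ratio_range[2]),
        dil_gen = sample(4:ap$max_generation, 6, replace = TRUE),
        defect_base = stats::runif(1, lp$subject_defect_range[1],
                                   lp$subject_defect_range[2])
      )
    })
    dil <- tibble::tibble(
      lobe = lobes[subj_draw$dilate],
      generation = subj_draw$dil_gen[subj_draw$dilate],
      ratio = subj_draw$ratio[subj_draw$dilate]
    )
    spec <- six_lobe_tree_spec(
      root_lumen_mm = ap$root_lumen_mm, taper = ap$taper, wall_mm = ap$wall_mm,
      max_generation = ap$max_generation,
      dilations = if (nrow(dil)) dil else NULL
    )
    for (vi in seq_along(visits)) {
      visit <- visits[vi]
      vseed <- derive_seed(cfg$seed, 3, si, vi)
      if ("phantom" %in% stages || "measure" %in% stages) {
        gf <- 1 + (ap$growth_rate_per_year %||% 0) * visit / 12
        spec_v <- spec
        spec_v$branches$lumen_diameter_mm <- spec$branches$lumen_diameter_mm * gf
        aph <- make_airway_phantom(spec_v, spacing = ap$spacing_mm,
                                   noise_sd = ap$noise_sd_hu, seed = vseed)
      }
      vfrac <- local_rng(derive_seed(cfg$seed, 4, si, vi))(
        pmin(0.5, pmax(0, stats::rnorm(6, subj_draw$defect_base,
                                       lp$visit_defect_sd)))
      )
      tspec <- trapping_spec(
        defect_fraction = stats::setNames(vfrac, lobes),
        insp_mean = lp$insp_mean, insp_sd = lp$insp_sd,
        exp_mean = lp$exp_mean, exp_sd = lp$exp_sd,
        defect_mean = lp$defect_mean, defect_sd = lp$defect_sd,
        blob_radius_mm = lp$blob_radius_mm, seed = vseed
      )
      lph <- make_paired_lung_phantom(geo, tspec)
      if (isTRUE(cfg$write_volumes)) {
        write_volume(aph$volume, file.path(out_dir, "phantoms",
                                           sprintf("%s_v%02d_airway.nii.gz", subj, visit)))
        write_volume(lph$insp, file.path(out_dir, "phantoms",
                                         sprintf("%s_v%02d_insp.nii.gz", subj, visit)))
        write_volume(lph$exp, file.path(out_dir, "phantoms",
                                        sprintf("%s_v%02d_exp.nii.gz", subj, visit)))
      }
      truth_rows[[paste(subj, visit)]] <- dplyr::mutate(
        lph$defect_fractions, subject = subj, timepoint_months = visit,
        .before = 1
      )
      if ("measure" %in% stages) {
        tree <- assign_lobes(label_generations(aph$tree), lobar_entries(spec))
        mt <- measure_tree(aph$volume, tree, mp)
        agg <- dplyr::bind_rows(lapply(lobes, function(lb) {
          aggregate_region(mt, c(5, min(10, ap$max_generation)), lb)
        }))
        bei <- dplyr::bind_rows(lapply(lobes, function(lb) {
          compute_bei(mt, lb, kappa = cfg$measurement$bei_kappa)
        }))
        utils::write.csv(
          tree_sections(mt),
          file.path(out_dir, "measures",
                    sprintf("%s_v%02d_sections.csv", subj, visit)),
          row.names = FALSE
        )
      }
      if ("trap" %in% stages) {
        at <- air_trapping_table(lph$insp, lph$exp, lph$mask, lph$mask,
                                 fractions = unlist(cfg$trapping$fractions))
        trap_rows[[paste(subj, visit)]] <- dplyr::mutate(
          at, subject = subj, timepoint_months = visit, .before = 1
        )
      }
      if ("stats" %in% stages) {
        a3 <- stats::setNames(at$A3[match(lobes, at$region)], lobes)
        cohort_rows[[paste(subj, visit)]] <- tibble::tibble(
          subject = subj, timepoint_months = visit,
          age_years = base_age[si] + visit / 12,
          region = lobes,
          BEI = bei$BEI[match(lobes, bei$region)],
          LA_5_10 = agg$LA_mm2[match(lobes, agg$region)],
          WP_5_10 = agg$WP_pct[match(lobes, agg$region)],
          A3 = unname(a3)
        )
      }
      if ("trap" %in% stages) {
        qc_rows[[paste(subj, visit)]] <- tibble::tibble(
          subject = subj, timepoint_months = visit,
          TLV_cm3 = at$TLV_cm3[at$region == "total"]
        )
      }
    }
    say("subject ", subj, " done")
  }

  outputs <- character(0)
  emit_csv <- function(df, rel) {
    p <- file.path(out_dir, rel)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, rel)
    p
  }
  emit_json <- function(obj, rel) {
    p <- file.path(out_dir, rel)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, rel)
    p
  }
  if (length(truth_rows)) {
    emit_csv(dplyr::bind_rows(truth_rows), "phantoms/defect_truth.csv")
  }
  result <- list()
  if ("trap" %in% stages) {
    trap_tab <- dplyr::bind_rows(trap_rows)
    emit_csv(trap_tab, "trapping/air_trapping.csv")
    result$trapping <- trap_tab
  }
  if ("stats" %in% stages) {
    cohort <- dplyr::bind_rows(cohort_rows)
    emit_csv(cohort, "stats/cohort.csv")
    result$cohort <- cohort
    # descriptive summary per endpoint and timepoint (Table-2 shape)
    desc <- tidyr::pivot_longer(
      cohort, cols = c("BEI", "LA_5_10", "WP_5_10", "A3"),
      names_to = "endpoint", values_to = "value"
    )
    desc <- dplyr::group_by(desc, .data$endpoint, .data$timepoint_months)
    desc <- dplyr::summarise(
      desc,
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
    emit_csv(desc, "stats/summary_by_timepoint.csv")
    result$summary <- desc
    # QC: lung-volume consistency per subject
    qc_tab <- dplyr::bind_rows(qc_rows)
    qc_list <- lapply(split(qc_tab, qc_tab$subject), function(df) {
      df <- df[order(df$timepoint_months), ]
      rep <- check_volume_consistency(df$TLV_cm3,
                                      cfg$qc$volume_change_threshold)
      list(subject = df$subject[1], pass = attr(rep, "pass"),
           pairs = as.data.frame(rep))
    })
    emit_json(unname(qc_list), "qc/volume_consistency.json")
    result$qc <- qc_list
    fits <- list()
    for (ep in cfg$stats$crosssectional_endpoints) {
      ft <- crosssectional_model(cohort, ep, robust = isTRUE(cfg$stats$robust))
      fits[[paste0("cross_", ep)]] <- ft
      emit_csv(tidy(ft), sprintf("stats/model_cross_%s.csv", ep))
    }
    for (iv in cfg$stats$longitudinal_intervals) {
      ep <- cfg$stats$longitudinal_endpoint
      ft <- longitudinal_model(cohort, ep, interval = iv,
                               robust = isTRUE(cfg$stats$robust))
      nm <- sprintf("long_%s_%d_%d", ep, iv[1], iv[2])
      fits[[nm]] <- ft
      emit_csv(tidy(ft), sprintf("stats/model_%s.csv", nm))
    }
    result$fits <- fits
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cfqct")),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(stats::setNames(outputs, outputs), function(rel) {
      unname(tools::md5sum(file.path(out_dir, rel)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete; manifest written")
  result$manifest <- manifest
  invisible(result)
}

ap_num <- function(x) as.integer(x)
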