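#' Default run configuration
#'
#' The defaults reproduce the study design: 4 control + 5 treated animals,
#' 7 examinations over 24 h, 2 operators, 3 replicates (378 ROIs), density
#' 1000 kg/m^3, 30% QC threshold, 80% FT threshold, 60-um SHG windows; one
#' treated animal loses its last examination (6 records) and 2 records
#' carry designed QC violations, mirroring the study's accounting.
#'
#' @return Nested named list understood by [validate_config()] /
#'   [run_study()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    rho = 1000,
    qc_threshold = 0.30,
    ft_threshold = 0.80,
    roi_um = 60,
    design = list(
      n_animals_control = 4L, n_animals_treated = 5L,
      hours = c(0, 4, 8, 12, 16, 20, 24),
      n_operators = 2L, n_replicates = 3L, pixels_per_roi = 200L
    ),
    control_model = list(a = 0.0014, b = -0.0648, c = 10.7016,
                         noise_sd_exam = 0.5, noise_sd_pixel_frac = 0.10),
    treated_model = list(a = 0.0103, b = -0.3844, c = 9.2147,
                         noise_sd_exam = 0.5, noise_sd_pixel_frac = 0.10),
    n_missing_exam_animals = 1L,  # animals losing the last examination
    n_qc_violations = 2L,
    qc_violation_frac = 0.40,
    shg = list(
      n_images_per_group = 10L,
      aligned = list(mean_orientation = 0, dispersion_sd = 3,
                     waviness_amp = 1, waviness_period = 25),
      disordered = list(mean_orientation = 0, dispersion_sd = 60,
                        waviness_amp = 4, waviness_period = 20,
                        bundle_spacing = 40)
    ),
    pge2 = list(n_per_group = 5L, fold_increase_treated = 10)
  )
}

#' Validate and normalise a run configuration
#'
#' Fills every missing field from [default_config()], rejects unknown keys
#' (reported with their path into the configuration), and checks ranges:
#' thresholds in (0, 1), strictly increasing hours, positive counts and
#' density.
#'
#' @param config Possibly partial nested list (e.g. from [load_config()]).
#' @return The normalised configuration.
#' @export
validate_config <- function(config = list()) {
  merged <- merge_config(default_config(), config, path = "config")
  check_number(merged$rho, "rho", lower = 0, strict_lower = TRUE)
  check_number(merged$qc_threshold, "qc_threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(merged$ft_threshold, "ft_threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(merged$roi_um, "roi_um", lower = 0, strict_lower = TRUE)
  ## these constructors enforce the remaining invariants
  do.call(swe_design, c(merged$design, list(seed = merged$seed)))
  do.call(trajectory_model, merged$control_model)
  do.call(trajectory_model, merged$treated_model)
  check_count(merged$n_missing_exam_animals, "n_missing_exam_animals", 0L)
  stop_if(merged$n_missing_exam_animals > merged$design$n_animals_treated,
          "n_missing_exam_animals exceeds the number of treated animals")
  check_count(merged$n_qc_violations, "n_qc_violations", 0L)
  check_count(merged$shg$n_images_per_group, "shg$n_images_per_group", 2L)
  check_count(merged$pge2$n_per_group, "pge2$n_per_group", 2L)
  merged
}

#' @noRd
merge_config <- function(defaults, user, path) {
  stop_if(!is.list(user), sprintf("'%s' must be a mapping", path))
  unknown <- setdiff(names(user), names(defaults))
  stop_if(length(unknown) > 0,
          sprintf("unknown configuration key(s): %s",
                  paste0(path, "$", unknown, collapse = ", ")))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                paste0(path, "$", nm))
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Load a YAML run configuration
#' @param path Path to a YAML file mirroring [default_config()]'s
#'   structure.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full synthetic study end to end
#'
#' Simulates the SWE exam table, runs ROI stiffness quantification with QC
#' and accounting, the longitudinal statistics (ANOVA-type statistic,
#' per-hour rank-sum tests with step-up correction, per-group quadratic
#' trajectory fits), intra- and inter-operator Bland-Altman agreement,
#' the SHG directionality branch (synthetic aligned vs disordered fibre
#' images, per-ROI R and brightest-10-pixel intensity, one-way ANOVA), and
#' the prostaglandin Kruskal-Wallis comparison. Fully deterministic under
#' the configured seed.
#'
#' @param config Configuration from [validate_config()] / [load_config()];
#'   partial lists are normalised first.
#' @param out_dir Optional output directory; when given, every figure-ready
#'   table is written as CSV plus a `report.json` with the full results and
#'   the echoed configuration.
#' @param verbose Log per-stage progress and record counts.
#' @return The report as a nested list (class `study_report`).
#' @export
run_study <- function(config = default_config(), out_dir = NULL,
                      verbose = TRUE) {
  config <- validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## --- simulate -----------------------------------------------------
  design <- do.call(swe_design, c(config$design, list(seed = config$seed)))
  exams <- stage("simulate-swe", {
    ctrl <- do.call(trajectory_model, config$control_model)
    trt <- do.call(trajectory_model, config$treated_model)
    n_tot <- n_records(design)
    ## the last examination of the last treated animal(s) is lost
    skeleton <- simulate_swe_dataset(design, ctrl, trt, rho = config$rho)
    last_hour <- max(design$hours)
    treated_animals <- unique(skeleton$animal[skeleton$group == "treated"])
    lost <- utils::tail(treated_animals, config$n_missing_exam_animals)
    missing_slots <- skeleton$record[skeleton$animal %in% lost &
                                       skeleton$hour == last_hour]
    set.seed(substream_seed(config$seed, "qc-slots"))
    qc_slots <- sort(sample(setdiff(seq_len(n_tot), missing_slots),
                            config$n_qc_violations))
    simulate_swe_dataset(design, ctrl, trt,
                         qc_violation_slots = qc_slots,
                         missing_slots = missing_slots,
                         qc_violation_frac = config$qc_violation_frac,
                         rho = config$rho)
  })
  say("simulate-swe: %d ROI records", nrow(exams))

  ## --- elasto -------------------------------------------------------
  summaries <- stage("analyze-swe",
                     summarize_exams(exams, rho = config$rho,
                                     qc_threshold = config$qc_threshold))
  exam_level <- stage("aggregate", aggregate_exams(summaries))
  accounting <- account_dataset(summaries)
  say("analyze-swe: %d exams, %d missing records, %d QC rejections",
      nrow(exam_level), accounting$n_rejected_missing,
      accounting$n_rejected_qc)

  ## --- longitudinal statistics -------------------------------------
  ## animal-level value per hour: mean of the operators' exam medians
  long <- stage("stats-longitudinal", {
    agg <- stats::aggregate(median_kpa ~ animal + group + hour,
                            data = exam_level, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
    names(agg)[names(agg) == "median_kpa"] <- "value"
    agg[!is.nan(agg$value), ]
  })
  ats <- stage("stats-ats", anova_type_statistic(long))
  hour_tests <- stage("stats-ranksum", ranksum_by_time(long))
  fits <- stage("stats-trajectory", fit_group_trajectories(exam_level))

  ## --- reproducibility ---------------------------------------------
  ba <- stage("stats-bland-altman", {
    wide <- stats::reshape(
      exam_level[, c("animal", "hour", "operator", "median_kpa")],
      idvar = c("animal", "hour"), timevar = "operator",
      direction = "wide")
    ops <- sort(unique(exam_level$operator))
    inter <- bland_altman(wide[[paste0("median_kpa.", ops[1])]],
                          wide[[paste0("median_kpa.", ops[2])]],
                          labels = paste(wide$animal, wide$hour, sep = "@"))
    ## intra-operator: replicate 1 vs replicate 2 ROI medians
    ok <- summaries[!summaries$missing & summaries$qc_pass %in% TRUE, ]
    r1 <- ok[ok$replicate == 1, ]
    r2 <- ok[ok$replicate == 2, ]
    key <- function(d) paste(d$animal, d$hour, d$operator, sep = "@")
    common <- intersect(key(r1), key(r2))
    intra <- bland_altman(r1$median_kpa[match(common, key(r1))],
                          r2$median_kpa[match(common, key(r2))],
                          labels = common)
    list(interoperator = inter, intraoperator = intra)
  })

  ## --- SHG branch ---------------------------------------------------
  shg <- stage("analyze-shg", {
    mk_params <- function(overrides) do.call(fibre_params, overrides)
    run_group <- function(label, overrides) {
      pars <- mk_params(overrides)
      tabs <- lapply(seq_len(config$shg$n_images_per_group), function(k) {
        img <- simulate_fibre_image(
          pars, seed = substream_seed(config$seed,
                                      paste0("shg-", label, "-", k)))
        cbind(group = label,
              analyze_shg_image(img, side_um = config$roi_um,
                                threshold = config$ft_threshold,
                                image_id = paste0(label, "_", k)))
      })
      do.call(rbind, tabs)
    }
    tab <- rbind(run_group("aligned", config$shg$aligned),
                 run_group("disordered", config$shg$disordered))
    list(rois = tab,
         r_test = compare_shg_groups(tab$R, tab$group),
         intensity_test = compare_shg_groups(tab$max10, tab$group))
  })
  say("analyze-shg: %d ROIs, R means %s",
      nrow(shg$rois),
      paste(sprintf("%s=%.3f", names(shg$r_test$group_means),
                    shg$r_test$group_means), collapse = ", "))

  ## --- PGE2 ---------------------------------------------------------
  pge2 <- stage("stats-pge2", {
    tab <- simulate_pge2_table(config$pge2$n_per_group,
                               config$pge2$fold_increase_treated,
                               seed = substream_seed(config$seed, "pge2-run"))
    t2 <- tab[tab$sample_time == "T2", ]
    list(table = tab, test = kruskal_wallis(t2$concentration, t2$group))
  })

  report <- structure(list(
    config = config,
    accounting = unclass(accounting),
    ats = ats,
    hour_tests = hour_tests,
    trajectory_fits = lapply(fits, function(f)
      f[c("a", "b", "c", "r_squared", "n")]),
    bland_altman = list(
      interoperator = ba$interoperator[c("mean_diff", "sd_diff", "loa_low",
                                         "loa_high", "coverage", "n")],
      intraoperator = ba$intraoperator[c("mean_diff", "sd_diff", "loa_low",
                                         "loa_high", "coverage", "n")]),
    shg = list(r_test = shg$r_test, intensity_test = shg$intensity_test),
    pge2_test = pge2$test
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_swe_csv(exams, file.path(out_dir, "exams.csv"))
    utils::write.csv(summaries, file.path(out_dir, "roi_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(exam_level, file.path(out_dir, "exam_medians.csv"),
                     row.names = FALSE)
    utils::write.csv(hour_tests, file.path(out_dir, "hour_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(ats, file.path(out_dir, "anova_type_statistics.csv"),
                     row.names = FALSE)
    utils::write.csv(ba$interoperator$table,
                     file.path(out_dir, "bland_altman_interoperator.csv"),
                     row.names = FALSE)
    utils::write.csv(ba$intraoperator$table,
                     file.path(out_dir, "bland_altman_intraoperator.csv"),
                     row.names = FALSE)
    utils::write.csv(shg$rois, file.path(out_dir, "shg_rois.csv"),
                     row.names = FALSE)
    utils::write.csv(pge2$table, file.path(out_dir, "pge2.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report written to %s", out_dir)
  }
  report
}

#' @noRd
report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.matrix(x)) return(as.data.frame(x))
    x
  }
  strip(unclass(report))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic ripening study report\n")
  cat(sprintf("  ROIs: %d (missing %g%%, QC-rejected %g%%)\n",
              x$accounting$n_total, x$accounting$pct_rejected_missing,
              x$accounting$pct_rejected_qc))
  cat("  ANOVA-type statistics:\n")
  for (i in seq_len(nrow(x$ats))) {
    cat(sprintf("    %-10s ATS = %6.2f, df1 = %.2f, p = %.3g\n",
                x$ats$effect[i], x$ats$statistic[i], x$ats$df1[i],
                x$ats$p[i]))
  }
  for (g in names(x$trajectory_fits)) {
    f <- x$trajectory_fits[[g]]
    cat(sprintf("  %s trajectory: %.4f t^2 %+.4f t %+.4f (R^2 = %.0f%%)\n",
                g, f$a, f$b, f$c, 100 * f$r_squared))
  }
  cat(sprintf("  SHG R: aligned %.3f vs disordered %.3f (ANOVA p = %.3g)\n",
              x$shg$r_test$group_means[["aligned"]],
              x$shg$r_test$group_means[["disordered"]],
              x$shg$r_test$p_value))
  cat(sprintf("  PGE2 Kruskal-Wallis: H = %.2f, p = %.3g\n",
              x$pge2_test$H, x$pge2_test$p))
  invisible(x)
}
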