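#' Describe the factorial design of a longitudinal SWE study
#'
#' The default design reproduces a two-group ripening experiment: 4 control
#' and 5 treated animals, examined every 4 hours over 24 hours (7 time
#' points) by 2 independent operators acquiring 3 replicate elastographic
#' images each, i.e. 9 x 7 x 2 x 3 = 378 ROI acquisitions.
#'
#' @param n_animals_control,n_animals_treated Animals per group (>= 0, at
#'   least one animal overall).
#' @param hours Examination times in hours since the first exam; strictly
#'   increasing.
#' @param n_operators,n_replicates Operators per exam and replicate images
#'   per operator.
#' @param pixels_per_roi Number of shear-wave-speed pixels sampled inside
#'   the 5-mm ROI on the elasticity map.
#' @param seed Integer master seed; a fixed seed makes every simulation from
#'   this design byte-identical.
#' @return An object of class `swe_design`.
#' @examples
#' d <- swe_design()
#' n_records(d) # 378
#' @export
swe_design <- function(n_animals_control = 4, n_animals_treated = 5,
                       hours = c(0, 4, 8, 12, 16, 20, 24),
                       n_operators = 2, n_replicates = 3,
                       pixels_per_roi = 200, seed = 1L) {
  n_animals_control <- check_count(n_animals_control, "n_animals_control", 0L)
  n_animals_treated <- check_count(n_animals_treated, "n_animals_treated", 0L)
  stop_if(n_animals_control + n_animals_treated < 1L,
          "the design must contain at least one animal")
  stop_if(!is.numeric(hours) || length(hours) < 1L || anyNA(hours) ||
            any(hours < 0) || is.unsorted(hours, strictly = TRUE),
          "'hours' must be non-negative and strictly increasing")
  structure(list(
    n_animals_control = n_animals_control,
    n_animals_treated = n_animals_treated,
    hours = as.numeric(hours),
    n_operators = check_count(n_operators, "n_operators"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    pixels_per_roi = check_count(pixels_per_roi, "pixels_per_roi"),
    seed = check_count(seed, "seed", 0L)
  ), class = "swe_design")
}

#' Number of ROI records a design generates
#' @param design A [swe_design()].
#' @return Integer product of the design factors.
#' @export
n_records <- function(design) {
  stopifnot(inherits(design, "swe_design"))
  (design$n_animals_control + design$n_animals_treated) *
    length(design$hours) * design$n_operators * design$n_replicates
}

#' Quadratic stiffness trajectory with noise components
#'
#' Group-level stiffness over ripening time is modelled as a quadratic
#' `E(t) = a t^2 + b t + c` (kPa, t in hours). `noise_sd_exam` is additive
#' Gaussian noise on the exam-level stiffness (kPa); `noise_sd_pixel_frac`
#' sets the within-ROI pixel dispersion as a fraction of the ROI median
#' modulus (the quantity the 30% quality-control rule tests).
#'
#' @param a,b,c Quadratic coefficients in kPa/h^2, kPa/h and kPa.
#' @param noise_sd_exam Exam-level noise SD in kPa (>= 0).
#' @param noise_sd_pixel_frac Within-ROI SD as a fraction of the median
#'   modulus (>= 0).
#' @return An object of class `trajectory_model`.
#' @seealso [control_trajectory()], [treated_trajectory()]
#' @export
trajectory_model <- function(a, b, c, noise_sd_exam = 0.5,
                             noise_sd_pixel_frac = 0.10) {
  check_number(a, "a"); check_number(b, "b"); check_number(c, "c")
  check_number(noise_sd_exam, "noise_sd_exam", lower = 0)
  check_number(noise_sd_pixel_frac, "noise_sd_pixel_frac", lower = 0)
  structure(list(a = a, b = b, c = c, noise_sd_exam = noise_sd_exam,
                 noise_sd_pixel_frac = noise_sd_pixel_frac),
            class = "trajectory_model")
}

#' Default group trajectories
#'
#' The control cervix keeps a nearly flat stiffness around 10.7 kPa
#' (`0.0014 t^2 - 0.0648 t + 10.7016`) while the treated cervix softens
#' steeply (`0.0103 t^2 - 0.3844 t + 9.2147`), dropping by about half over
#' 24 h.
#'
#' @param noise_sd_exam,noise_sd_pixel_frac Noise components, see
#'   [trajectory_model()].
#' @return A `trajectory_model`.
#' @export
control_trajectory <- function(noise_sd_exam = 0.5,
                               noise_sd_pixel_frac = 0.10) {
  trajectory_model(0.0014, -0.0648, 10.7016, noise_sd_exam,
                   noise_sd_pixel_frac)
}

#' @rdname control_trajectory
#' @export
treated_trajectory <- function(noise_sd_exam = 0.5,
                               noise_sd_pixel_frac = 0.10) {
  trajectory_model(0.0103, -0.3844, 9.2147, noise_sd_exam,
                   noise_sd_pixel_frac)
}

#' Evaluate the noise-free trajectory
#' @param model A [trajectory_model()].
#' @param hours Numeric vector of times (h).
#' @return Stiffness in kPa.
#' @export
predict_trajectory <- function(model, hours) {
  stopifnot(inherits(model, "trajectory_model"))
  model$a * hours^2 + model$b * hours + model$c
}

## Bounded symmetric multiplicative deviates rescaled so that the sample
## median equals `centre` and the sample SD equals `sd_frac * centre`
## exactly. |z| is capped at 1.8 pre-standardisation, which keeps every
## sample positive for sd_frac < ~0.45.
#' @noRd
dial_pixel_moduli <- function(centre, sd_frac, n) {
  if (n == 1L || sd_frac == 0) return(rep(centre, n))
  z <- stats::qnorm(stats::runif(n, stats::pnorm(-1.8), stats::pnorm(1.8)))
  z <- z - stats::median(z)
  s <- stats::sd(z)
  if (s == 0) return(rep(centre, n))
  centre + z * (sd_frac * centre / s)
}

#' Simulate a full longitudinal SWE exam table
#'
#' Generates one ROI record per design cell (animal x hour x operator x
#' replicate). For each record the exam-level stiffness is the group
#' trajectory at that hour plus Gaussian exam noise; per-pixel shear-wave
#' speeds are then drawn so that the ROI median modulus equals the exam
#' stiffness and the within-ROI SD equals the requested fraction of it.
#' Records listed in `qc_violation_slots` get a dispersion of
#' `qc_violation_frac` (> 30% of the median), so the downstream
#' quality-control filter rejects exactly those; records in `missing_slots`
#' carry no pixel samples (emulating acquisitions lost to animal movement).
#'
#' @param design A [swe_design()].
#' @param control_model,treated_model [trajectory_model()]s per group; each
#'   must predict strictly positive stiffness at every design hour.
#' @param qc_violation_slots Integer record indices (row numbers in the
#'   returned table) whose within-ROI dispersion is dialled above the QC
#'   threshold.
#' @param missing_slots Integer record indices with no usable samples.
#' @param qc_violation_frac SD fraction used on violation slots (default
#'   0.40).
#' @param rho Tissue density in kg/m^3 used to convert moduli to shear-wave
#'   speeds.
#' @return A data.frame of class `swe_exams` with design columns
#'   `record, animal, group, hour, operator, replicate` and inline sample
#'   columns `sws_001 ...` (m/s). Attributes `design`, `qc_violation_slots`
#'   and `missing_slots` record the generating conditions.
#' @examples
#' exams <- simulate_swe_dataset(swe_design(seed = 7))
#' nrow(exams) # 378
#' @export
simulate_swe_dataset <- function(design,
                                 control_model = control_trajectory(),
                                 treated_model = treated_trajectory(),
                                 qc_violation_slots = integer(),
                                 missing_slots = integer(),
                                 qc_violation_frac = 0.40,
                                 rho = 1000) {
  stopifnot(inherits(design, "swe_design"))
  check_number(qc_violation_frac, "qc_violation_frac", lower = 0.30,
               strict_lower = TRUE)
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  for (nm in c("control", "treated")) {
    m <- if (nm == "control") control_model else treated_model
    stopifnot(inherits(m, "trajectory_model"))
    bad <- design$hours[predict_trajectory(m, design$hours) <= 0]
    stop_if(length(bad) > 0,
            sprintf("%s trajectory predicts non-positive stiffness at t = %s h",
                    nm, paste(bad, collapse = ", ")))
  }

  animals <- c(if (design$n_animals_control > 0)
                 paste0("C", seq_len(design$n_animals_control)),
               if (design$n_animals_treated > 0)
                 paste0("T", seq_len(design$n_animals_treated)))
  groups <- rep(c("control", "treated"),
                c(design$n_animals_control, design$n_animals_treated))

  grid <- expand.grid(
    replicate = seq_len(design$n_replicates),
    operator = paste0("op", seq_len(design$n_operators)),
    hour = design$hours,
    animal_i = seq_along(animals),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  ## animal-major, then hour, operator, replicate
  grid <- grid[order(grid$animal_i, grid$hour, grid$operator, grid$replicate), ]
  n <- nrow(grid)
  stop_if(any(qc_violation_slots < 1 | qc_violation_slots > n),
          "qc_violation_slots outside the record range")
  stop_if(any(missing_slots < 1 | missing_slots > n),
          "missing_slots outside the record range")
  stop_if(length(intersect(qc_violation_slots, missing_slots)) > 0,
          "a record cannot be both missing and a QC violation")

  set.seed(substream_seed(design$seed, "swe-exams"))
  p <- design$pixels_per_roi
  sws <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    mdl <- if (groups[grid$animal_i[i]] == "control") control_model
           else treated_model
    e_exam <- predict_trajectory(mdl, grid$hour[i]) +
      stats::rnorm(1, 0, mdl$noise_sd_exam)
    e_exam <- max(e_exam, 0.05) # stiffness cannot be negative
    if (i %in% missing_slots) next
    frac <- if (i %in% qc_violation_slots) qc_violation_frac
            else mdl$noise_sd_pixel_frac
    e_px <- dial_pixel_moduli(e_exam, frac, p)
    sws[i, ] <- modulus_to_sws(e_px, rho = rho)
  }

  out <- data.frame(
    record = seq_len(n),
    animal = animals[grid$animal_i],
    group = groups[grid$animal_i],
    hour = grid$hour,
    operator = grid$operator,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  colnames(sws) <- sprintf("sws_%03d", seq_len(p))
  out <- cbind(out, as.data.frame(sws))
  attr(out, "design") <- design
  attr(out, "qc_violation_slots") <- as.integer(sort(qc_violation_slots))
  attr(out, "missing_slots") <- as.integer(sort(missing_slots))
  class(out) <- c("swe_exams", "data.frame")
  out
}

#' Extract the shear-wave-speed sample matrix from an exam table
#' @param exams A `swe_exams` data.frame (or any data.frame with `sws_*`
#'   columns).
#' @return Numeric matrix, one row per record.
#' @export
sws_samples <- function(exams) {
  cols <- grep("^sws_", names(exams), value = TRUE)
  stop_if(length(cols) == 0, "no 'sws_*' sample columns found")
  as.matrix(exams[, cols, drop = FALSE])
}

#' Write / read the SWE exam CSV dialect
#'
#' One row per ROI with the design columns followed by inline `sws_*`
#' sample columns; UTF-8, header mandatory.
#'
#' @param exams A `swe_exams` data.frame.
#' @param path Output path.
#' @return `write_swe_csv` returns `path` invisibly; `read_swe_csv` returns
#'   a `swe_exams` data.frame.
#' @export
write_swe_csv <- function(exams, path) {
  utils::write.csv(as.data.frame(exams), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_swe_csv
#' @export
read_swe_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("animal", "group", "hour", "operator", "replicate")
  miss <- setdiff(need, names(out))
  stop_if(length(miss) > 0,
          paste("exam CSV lacks columns:", paste(miss, collapse = ", ")))
  class(out) <- c("swe_exams", "data.frame")
  out
}

#' Simulate a prostaglandin (PGE2 metabolite) assay table
#'
#' Two plasma samples per animal: T1 before induction and T2 24 h after.
#' Treated animals' T2 concentration is scaled by `fold_increase_treated`
#' (a sharp PGE2 surge follows induction); control T2 stays at baseline.
#'
#' @param n_per_group Animals per group (>= 2 so a group test is possible).
#' @param fold_increase_treated Multiplicative T2/T1 effect in the treated
#'   group (> 0).
#' @param seed Integer seed.
#' @param baseline Median baseline concentration (pg/mL).
#' @param cv Lognormal coefficient of variation of baselines and of the
#'   residual sampling noise.
#' @return A data.frame `animal, group, sample_time, concentration`.
#' @export
simulate_pge2_table <- function(n_per_group, fold_increase_treated, seed = 1L,
                                baseline = 50, cv = 0.25) {
  n_per_group <- check_count(n_per_group, "n_per_group", 2L)
  check_number(fold_increase_treated, "fold_increase_treated", lower = 0,
               strict_lower = TRUE)
  set.seed(substream_seed(seed, "pge2"))
  sdlog <- sqrt(log(1 + cv^2))
  mk <- function(group, prefix, fold) {
    t1 <- stats::rlnorm(n_per_group, log(baseline), sdlog)
    t2 <- t1 * fold * stats::rlnorm(n_per_group, 0, sdlog / 4)
    data.frame(
      animal = rep(paste0(prefix, seq_len(n_per_group)), 2L),
      group = group,
      sample_time = rep(c("T1", "T2"), each = n_per_group),
      concentration = c(t1, t2),
      stringsAsFactors = FALSE
    )
  }
  rbind(mk("control", "C", 1), mk("treated", "T", fold_increase_treated))
}
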