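test_that("record count is the product of the design factors", {
  designs <- list(
    swe_design(),                                   # 9 x 7 x 2 x 3 = 378
    swe_design(2, 3, hours = c(0, 6), n_operators = 1, n_replicates = 2,
               pixels_per_roi = 10),
    swe_design(1, 0, hours = 0, n_operators = 1, n_replicates = 1,
               pixels_per_roi = 5)
  )
  for (d in designs) {
    ex <- simulate_swe_dataset(d)
    expect_equal(nrow(ex), n_records(d))
  }
  expect_equal(n_records(swe_design()), 378)
})

test_that("zero noise recovers the trajectory polynomial exactly", {
  d <- swe_design(1, 0, hours = 0, n_operators = 1, n_replicates = 1,
                  pixels_per_roi = 8, seed = 3)
  quiet <- trajectory_model(0, 0, 10.7016, noise_sd_exam = 0,
                            noise_sd_pixel_frac = 0)
  ex <- simulate_swe_dataset(d, control_model = quiet)
  expect_equal(nrow(ex), 1L)
  est <- summarize_roi(sws_samples(ex)[1, ])
  expect_equal(est$median_modulus, 10.7016, tolerance = 1e-12)

  # full design, every ROI median equals the polynomial at its hour
  d2 <- swe_design(2, 2, pixels_per_roi = 20, seed = 5)
  ctrl <- control_trajectory(noise_sd_exam = 0, noise_sd_pixel_frac = 0)
  trt <- treated_trajectory(noise_sd_exam = 0, noise_sd_pixel_frac = 0)
  ex2 <- simulate_swe_dataset(d2, ctrl, trt)
  s <- summarize_exams(ex2)
  expected <- ifelse(s$group == "control",
                     predict_trajectory(ctrl, s$hour),
                     predict_trajectory(trt, s$hour))
  expect_equal(s$median_kpa, expected, tolerance = 1e-9)
})

test_that("designed QC violations, and only those, are rejected downstream", {
  slots <- c(10, 200)
  ex <- simulate_swe_dataset(swe_design(seed = 7),
                             qc_violation_slots = slots)
  s <- summarize_exams(ex)
  expect_equal(which(s$qc_pass %in% FALSE), slots)
  acc <- account_dataset(s)
  expect_equal(acc$n_rejected_qc, 2L)
})

test_that("a fixed seed reproduces the exam table byte for byte", {
  a <- simulate_swe_dataset(swe_design(seed = 11), missing_slots = 1:3)
  b <- simulate_swe_dataset(swe_design(seed = 11), missing_slots = 1:3)
  expect_identical(a, b)
  c_ <- simulate_swe_dataset(swe_design(seed = 12), missing_slots = 1:3)
  expect_false(identical(a$sws_001, c_$sws_001))
})

test_that("invalid trajectories and slots are rejected with diagnostics", {
  sinking <- trajectory_model(0, -1, 5)  # negative by t = 5 h
  expect_error(simulate_swe_dataset(swe_design(), control_model = sinking),
               "non-positive stiffness")
  expect_error(simulate_swe_dataset(swe_design(), qc_violation_slots = 1e5),
               "record range")
  expect_error(swe_design(hours = c(4, 0)), "strictly increasing")
  expect_error(trajectory_model(1, 1, 1, noise_sd_exam = -1), "range")
})

test_that("exam CSV round trip preserves the table", {
  ex <- simulate_swe_dataset(swe_design(2, 1, hours = c(0, 8),
                                        pixels_per_roi = 6, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_swe_csv(ex, path)
  back <- read_swe_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ex),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("prostaglandin table shows the designed fold increase at T2", {
  tab <- simulate_pge2_table(5, fold_increase_treated = 10, seed = 4)
  expect_equal(nrow(tab), 20L)
  ratio <- function(g) {
    t1 <- tab$concentration[tab$group == g & tab$sample_time == "T1"]
    t2 <- tab$concentration[tab$group == g & tab$sample_time == "T2"]
    median(t2 / t1)
  }
  expect_equal(ratio("treated"), 10, tolerance = 0.35 * 10)
  expect_equal(ratio("control"), 1, tolerance = 0.35)

  expect_identical(simulate_pge2_table(3, 2, seed = 9),
                   simulate_pge2_table(3, 2, seed = 9))
  expect_error(simulate_pge2_table(1, 2), "integer >= 2")

  # null case: no fold change leaves the groups exchangeable at T2
  null_tab <- simulate_pge2_table(6, 1, seed = 5)
  t2 <- null_tab[null_tab$sample_time == "T2", ]
  kw <- kruskal_wallis(t2$concentration, t2$group)
  expect_gt(kw$p, 0.05)
})
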