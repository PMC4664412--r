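test_that("normalize_volumes divides by ICV exactly", {
  rec <- data.frame(icv_mm3 = 1.5e6, hippocampal_mm3 = 4950,
                    frontal_mm3 = 33000, temporal_mm3 = 0,
                    parietal_mm3 = 19000)
  out <- normalize_volumes(rec)
  expect_equal(out$hippocampal, 0.0033)
  expect_equal(out$temporal, 0)

  set.seed(11)
  n <- 50
  rnd <- data.frame(icv_mm3 = runif(n, 1.2e6, 1.8e6),
                    hippocampal_mm3 = runif(n, 3000, 6000),
                    frontal_mm3 = runif(n, 2e4, 4e4),
                    temporal_mm3 = runif(n, 1e4, 2e4),
                    parietal_mm3 = runif(n, 1e4, 2.5e4))
  got <- normalize_volumes(rnd)
  for (roi in c("hippocampal", "frontal", "temporal", "parietal")) {
    expect_identical(got[[roi]], rnd[[paste0(roi, "_mm3")]] / rnd$icv_mm3)
  }
})

test_that("normalize_volumes validates its inputs by name", {
  rec <- data.frame(icv_mm3 = 0, hippocampal_mm3 = 4950,
                    frontal_mm3 = 1, temporal_mm3 = 1, parietal_mm3 = 1)
  expect_error(normalize_volumes(rec), "icv_mm3",
               class = "adsubtype_validation_error")
  expect_error(normalize_volumes(rec[-2]), "hippocampal_mm3",
               class = "adsubtype_validation_error")
})

test_that("assign_stratum picks the nearest midpoint, ties to younger", {
  spec <- default_strata()
  # midpoints 62.5, 72.5, 77.5, 82.5
  expect_identical(assign_stratum(60, spec), 1L)
  expect_identical(assign_stratum(72.5, spec), 2L)
  # equidistant between midpoints 62.5 and 72.5 -> younger stratum
  expect_identical(assign_stratum(67.5, spec), 1L)

  sweep <- assign_stratum(seq(55, 90, by = 0.1), spec)
  expect_true(all(diff(sweep) >= 0))

  expect_error(assign_stratum(54, spec), class = "adsubtype_range_error")
  expect_warning(got <- assign_stratum(95, spec, clamp = TRUE), "clamped")
  expect_identical(got, 4L)
})

test_that("norm cells hold sample mean and n-1 SD over interval members", {
  set.seed(21)
  n <- 400
  cn <- make_cn_grid(n)
  # single-stratum spec: hand check against direct mean/sd
  spec1 <- strata_spec(55, 90, min_stratum_n = 10)
  norm1 <- build_norm_table(cn, spec1)
  ratios <- normalize_volumes(cn)
  for (g in c("female", "male")) {
    idx <- cn$gender == g
    cell <- norm1[norm1$gender == g & norm1$roi == "hippocampal", ]
    expect_equal(cell$mean, mean(ratios$hippocampal[idx]))
    expect_equal(cell$sd, sd(ratios$hippocampal[idx]))
    expect_equal(cell$n, sum(idx))
  }

  # with overlapping strata a subject inside two intervals is in both cells
  spec <- default_strata(min_stratum_n = 5)
  norm <- build_norm_table(cn, spec)
  n1 <- norm$n[norm$stratum == 1 & norm$gender == "female"][1]
  n2 <- norm$n[norm$stratum == 2 & norm$gender == "female"][1]
  shared <- sum(cn$age >= 65 & cn$age <= 70 & cn$gender == "female")
  expect_gt(shared, 0)
  expect_equal(sum(cn$gender == "female" & cn$age <= 70), n1)
  expect_equal(sum(cn$gender == "female" & cn$age >= 65 & cn$age <= 80), n2)
})

test_that("norm cell means match the generating mean within 3 SE", {
  set.seed(31)
  n <- 400
  cn <- data.frame(
    subject_id = sprintf("S%03d", 1:n), age = runif(n, 55, 90),
    gender = "female", diagnosis = "CN", icv_mm3 = 1.4e6,
    stringsAsFactors = FALSE
  )
  for (roi in c("hippocampal", "frontal", "temporal", "parietal")) {
    cn[[paste0(roi, "_mm3")]] <- rnorm(n, 0.0040, 0.0005) * cn$icv_mm3
  }
  norm <- build_norm_table(cn, strata_spec(55, 90, genders = "female",
                                           min_stratum_n = 10))
  cell <- norm[norm$roi == "hippocampal", ]
  expect_lt(abs(cell$mean - 0.0040), 3 * 0.0005 / sqrt(n))
})

test_that("degenerate and under-filled norm cells are refused", {
  cn <- make_cn_grid(60)
  # identical volumes in a cell -> zero variance
  flat <- cn
  flat$hippocampal_mm3 <- 0.0040 * flat$icv_mm3
  flat$icv_mm3 <- 1.4e6
  flat$hippocampal_mm3 <- 0.0040 * 1.4e6
  expect_error(build_norm_table(flat, strata_spec(55, 90, min_stratum_n = 5)),
               class = "adsubtype_degenerate_norm_error")

  # an empty gender level cannot reach min_stratum_n
  fem <- cn[cn$gender == "female", ]
  expect_error(build_norm_table(fem, strata_spec(55, 90, min_stratum_n = 5)),
               "male", class = "adsubtype_insufficient_norm_error")
  expect_error(build_norm_table(cn[0, ], strata_spec(55, 90)),
               class = "adsubtype_insufficient_norm_error")
})

test_that("z profiles standardize linearly against the matched cell", {
  cn <- make_cn_grid(300)
  spec <- strata_spec(55, 90, min_stratum_n = 10)
  norm <- build_norm_table(cn, spec)
  cell <- norm[norm$gender == "female" & norm$roi == "hippocampal", ]
  subj <- data.frame(
    subject_id = "T1", age = 70, gender = "female", diagnosis = "AD",
    icv_mm3 = 1.4e6,
    hippocampal_mm3 = cell$mean * 1.4e6,
    frontal_mm3 = 0.022 * 1.4e6, temporal_mm3 = 0.012 * 1.4e6,
    parietal_mm3 = 0.013 * 1.4e6, stringsAsFactors = FALSE
  )
  z <- compute_z_profiles(subj, norm)
  expect_equal(z$z_h, 0, tolerance = 1e-12)

  subj$hippocampal_mm3 <- (cell$mean - 2.20 * cell$sd) * 1.4e6
  z2 <- compute_z_profiles(subj, norm)
  expect_equal(z2$z_h, -2.20, tolerance = 1e-9)
})

test_that("z of a CN cohort against its own norms has cell mean 0, sd 1", {
  cn <- make_cn_grid(600, seed = 41)
  spec <- non_overlapping_strata()
  norm <- build_norm_table(cn, spec)
  z <- compute_z_profiles(cn, norm)
  gender <- cn$gender
  for (s in unique(z$stratum)) {
    for (g in c("female", "male")) {
      idx <- z$stratum == s & gender == g
      for (col in c("z_h", "z_f", "z_t", "z_p")) {
        expect_lt(abs(mean(z[[col]][idx])), 1e-9)
        expect_lt(abs(sd(z[[col]][idx]) - 1), 1e-9)
      }
    }
  }
})

test_that("z is scale invariant and decreasing in raw volume", {
  cn <- make_cn_grid(300, seed = 51)
  spec <- default_strata(min_stratum_n = 5)
  norm <- build_norm_table(cn, spec)
  subj <- cn[1:20, ]
  subj$diagnosis <- "AD"
  z1 <- compute_z_profiles(subj, norm)

  # common rescaling of every volume and every ICV leaves Z unchanged
  scaled_cn <- cn
  scaled_subj <- subj
  for (col in c("icv_mm3", "hippocampal_mm3", "frontal_mm3",
                "temporal_mm3", "parietal_mm3")) {
    scaled_cn[[col]] <- cn[[col]] * 3.7
    scaled_subj[[col]] <- subj[[col]] * 3.7
  }
  z2 <- compute_z_profiles(scaled_subj, build_norm_table(scaled_cn, spec))
  for (col in c("z_h", "z_f", "z_t", "z_p")) {
    expect_equal(z2[[col]], z1[[col]], tolerance = 1e-9)
  }

  # strictly decreasing in raw ROI volume, all else fixed
  bigger <- subj
  bigger$hippocampal_mm3 <- bigger$hippocampal_mm3 + 100
  z3 <- compute_z_profiles(bigger, norm)
  expect_true(all(z3$z_h > z1$z_h))
  expect_equal(z3$z_f, z1$z_f)
})

test_that("norm table CSV round trip is lossless", {
  cn <- make_cn_grid(200, seed = 61)
  norm <- build_norm_table(cn, default_strata(min_stratum_n = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_norm_table(norm, path)
  back <- read_norm_table(path)
  expect_identical(back$mean, norm$mean)
  expect_identical(back$sd, norm$sd)
  expect_identical(back$n, norm$n)
  spec2 <- attr(back, "strata_spec")
  expect_identical(spec2$lower, attr(norm, "strata_spec")$lower)
})
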