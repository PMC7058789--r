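test_that("tumour generation is deterministic and seed-sensitive", {
  sp <- test_specs()$MCN
  a <- generate_tumor(sp, seed = 7)
  b <- generate_tumor(sp, seed = 7)
  c <- generate_tumor(sp, seed = 8)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("single-level spec yields a constant ROI with zero entropy", {
  sp <- class_spec("SCA", hist_levels_active = 1)
  tm <- generate_tumor(sp, seed = 3)
  roi <- tm$volume$data[tm$mask$data]
  expect_equal(length(unique(roi)), 1L)
  q <- quantize_roi(tm$volume, tm$mask)
  h <- histogram_features(q)
  expect_equal(unname(h["Entropy"]), 0)
  expect_equal(unname(h["Uniformity"]), 1)
})

test_that("planted histogram skewness is recovered with the right sign", {
  sp_neg <- class_spec("SCA", hist_skew = -1, hist_levels_active = 40)
  sp_pos <- class_spec("SCA", hist_skew = 1, hist_levels_active = 40)
  sk <- function(sp) vapply(1:50, function(s) {
    tm <- generate_tumor(sp, shape_mm = c(30, 30, 40), seed = s)
    samp_skew(tm$volume$data[tm$mask$data])
  }, numeric(1))
  expect_lt(mean(sk(sp_neg)), -0.2)
  expect_gt(mean(sk(sp_pos)), 0.2)
})

test_that("degenerate spacing or extents are rejected", {
  sp <- test_specs()$SCA
  expect_error(generate_tumor(sp, spacing = c(0, 1, 5)), "invalid argument")
  expect_error(generate_tumor(sp, shape_mm = c(2, 2, 2)), "invalid argument")
})

test_that("clinical draws follow the class-conditional distributions", {
  spF <- class_spec("MCN", female_prob = 1)
  expect_true(all(vapply(1:10, function(s)
    generate_clinical(spF, s)$sex, character(1)) == "F"))

  sp0 <- class_spec("SCA", ca199_log_mean = log(9.6), ca199_log_sd = 0)
  expect_equal(generate_clinical(sp0, 1)$ca199, 9.6, tolerance = 1e-12)

  sp1 <- class_spec("SCA", ca199_log_mean = log(9.6), ca199_log_sd = 1)
  med <- median(vapply(1:1000, function(s)
    generate_clinical(sp1, s)$ca199, numeric(1)))
  expect_lt(abs(med - 9.6) / 9.6, 0.15)

  cl <- generate_clinical(test_specs()$IPMN, 4)
  expect_true(cl$age >= 18 && cl$age <= 90)
  expect_true(all(c(cl$ca199, cl$cea, cl$alt, cl$fbg, cl$max_diameter) > 0))
  expect_true(cl$blood_type %in% c("A", "B", "AB", "O"))
})

test_that("cohorts have exact class sizes, determinism and seed sensitivity", {
  specs <- test_specs()
  small <- generate_cohort(c(1, 1, 1), specs, seed = 2,
                           shape_mm = c(30, 30, 40))
  expect_length(small$cases, 3)
  expect_setequal(small$labels, c("SCA", "MCN", "IPMN"))

  c1 <- generate_cohort(c(2, 2, 2), specs, seed = 5, shape_mm = c(30, 30, 40))
  c2 <- generate_cohort(c(2, 2, 2), specs, seed = 5, shape_mm = c(30, 30, 40))
  c3 <- generate_cohort(c(2, 2, 2), specs, seed = 6, shape_mm = c(30, 30, 40))
  expect_identical(c1$cases[[4]]$volume$data, c2$cases[[4]]$volume$data)
  expect_identical(clinical_table(c1), clinical_table(c2))
  expect_false(identical(c1$cases[[4]]$volume$data, c3$cases[[4]]$volume$data))
  # every mask non-empty and inside its grid
  for (cs in c1$cases) {
    expect_gt(sum(cs$mask$data), 0)
    expect_identical(dim(cs$mask$data), dim(cs$volume$data))
  }
})

test_that("a cohort round-trips through the on-disk layout", {
  co <- generate_cohort(c(1, 1, 1), test_specs(), seed = 9,
                        shape_mm = c(30, 30, 40))
  dir <- tempfile("cohort")
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  rc <- read_case(file.path(dir, man$cases[[2]]$volume),
                  file.path(dir, man$cases[[2]]$mask))
  expect_identical(rc$volume$data, co$cases[[2]]$volume$data)
  expect_identical(rc$mask$data, co$cases[[2]]$mask$data)
  unlink(dir, recursive = TRUE)
})
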