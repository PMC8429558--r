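test_that("anthropometric quantities match their definitions", {
  expect_equal(compute_bmi(49.5, 1.5), 22.0)
  expect_equal(compute_bmi(63.0, 1.75), 63 / 3.0625)
  expect_error(compute_bmi(0, 1.7), "positive")
  expect_error(compute_bmi(60, -1), "positive")

  th <- als_thresholds()
  expect_equal(percent_ibw(22.0, th), 1.0)
  expect_equal(percent_ibw(19.8, th), 0.9)
  expect_equal(percent_ibw(17.6, th), 0.8)
  expect_error(percent_ibw(-1), "positive")

  expect_equal(delta_bmi(24, 24, 12), 0.0)
  expect_equal(delta_bmi(24, 21, 15), -0.2)
  expect_equal(delta_bmi(20, 19, 8), -0.125)
  expect_error(delta_bmi(24, 21, 0), "positive")

  expect_equal(delta_alsfrs(48, 10), 0.0)
  expect_equal(delta_alsfrs(36, 12), 1.0)
  expect_equal(delta_alsfrs(39, 15), 0.6)
  expect_error(delta_alsfrs(49, 10), "between 0 and 48")
  expect_error(delta_alsfrs(40, -2), "positive")
})

test_that("calorimetry quantities match Weir, RQ and Harris-Benedict", {
  expect_equal(respiratory_quotient(250, 200), 0.8)
  expect_equal(respiratory_quotient(300, 300), 1.0)
  expect_equal(respiratory_quotient(250, 175), 0.7)
  expect_error(respiratory_quotient(0, 100), "positive")

  expect_equal(weir_mree(0, 0), 0)
  expect_equal(weir_mree(250, 200), 1.44 * (3.941 * 250 + 1.106 * 200))
  expect_equal(weir_mree(200, 160), 1389.8304)
  expect_error(weir_mree(-1, 100), "non-negative")
  # linearity: doubling both gas volumes doubles mREE
  for (v in list(c(180, 150), c(260, 210), c(300, 240)))
    expect_equal(weir_mree(2 * v[1], 2 * v[2]), 2 * weir_mree(v[1], v[2]))

  expect_equal(harris_benedict_pree("male", 70, 170, 60),
               66.4730 + 13.7516 * 70 + 5.0033 * 170 - 6.7550 * 60)
  expect_equal(harris_benedict_pree("F", 50, 155, 70),
               655.0955 + 9.5634 * 50 + 1.8496 * 155 - 4.6756 * 70)
  # linearity in age (female coefficient)
  expect_equal(harris_benedict_pree("F", 50, 155, 71) -
                 harris_benedict_pree("F", 50, 155, 70), -4.6756)
  expect_error(harris_benedict_pree("X", 50, 155, 70), "sex")
})

test_that("BMM index pivots at its reference values and is sign-symmetric", {
  expect_equal(bmm_index(19.8, 45.0), 0.0)
  expect_equal(bmm_index(25.0, 38.0), 0.0)
  expect_equal(bmm_index(22.0, 40.6), 5.72)
  expect_equal(bmm_index(18.0, 34.5), 6.3)  # malnourished + normometabolic
  expect_true(is.na(bmm_index(NA, 40)))
  # invariant under (19.8 + a, 38 + b) <-> (19.8 - a, 38 - b)
  set.seed(42)
  a <- runif(20, -4, 4); b <- runif(20, -8, 8)
  expect_equal(bmm_index(19.8 + a, 38 + b), bmm_index(19.8 - a, 38 - b))
})

test_that("classify_profile derives all fields with documented boundaries", {
  rec <- make_records(6)
  prof <- classify_profile(rec)
  expect_equal(prof$bmi, rec$admission_weight / rec$height^2)
  expect_equal(prof$pct_ibw, prof$bmi / 22)
  expect_equal(prof$mree, weir_mree(rec$vo2, rec$vco2))
  expect_equal(prof$mree_per_lstm, prof$mree / rec$lstm)
  expect_equal(prof$bmm, (prof$bmi - 19.8) * (prof$mree_per_lstm - 38))

  # boundary conventions on constructed exact-boundary patients
  boundary <- make_records(3)
  boundary$height <- 1.5
  boundary$admission_weight <- 19.8 * 1.5^2          # pct_ibw exactly 0.9
  boundary$premorbid_weight <- boundary$admission_weight / 0.9  # exactly 10% loss
  boundary$lstm <- weir_mree(boundary$vo2, boundary$vco2) / 38  # ratio exactly 38
  boundary$ldl <- 100
  bp <- classify_profile(boundary)
  expect_false(any(bp$malnourished))        # %IBW < 0.9 is an open bound
  expect_true(all(bp$hypermetabolic))       # mREE/LSTM >= 38 is closed
  expect_false(any(bp$excess_weight_loss))  # 'more than 10%' is strict
  expect_true(all(bp$high_ldl))             # LDL >= 100 is closed
})

test_that("missing inputs yield missing derived values, never dropped rows", {
  rec <- make_records(4)
  rec$lstm[1] <- NA
  rec$ldl[2] <- NA
  rec$body_fat_pct[3] <- NA
  prof <- classify_profile(rec)
  expect_equal(nrow(prof), 4)
  expect_true(is.na(prof$mree_per_lstm[1]) && is.na(prof$bmm[1]) &&
                is.na(prof$high_bmm[1]) && is.na(prof$hypermetabolic[1]))
  expect_true(is.na(prof$high_ldl[2]))
  expect_true(is.na(prof$high_fat[3]))
  # fields with complete inputs are still derived on those rows
  expect_false(anyNA(prof$bmi))
  expect_false(is.na(prof$bmm[2]))
})

test_that("classify_profile is deterministic, idempotent, and partitions cohorts", {
  params <- synth_params(n = 120, seed = 7)
  rec <- generate_cohort(params)
  attr(rec, "true_bmm") <- attr(rec, "true_loghr") <- NULL
  p1 <- classify_profile(rec)
  p2 <- classify_profile(p1)  # rerun on own output
  expect_identical(p1, p2[names(p1)])

  # malnutrition equivalence: pct_ibw < 0.9 iff bmi < 19.8
  ok <- !is.na(p1$pct_ibw)
  expect_identical(p1$pct_ibw[ok] < 0.9, p1$bmi[ok] < 19.8)

  # complete rows partition into exactly the four nutrition x metabolism cells
  complete <- !is.na(p1$malnourished) & !is.na(p1$hypermetabolic)
  cells <- table(p1$malnourished[complete], p1$hypermetabolic[complete])
  expect_equal(sum(cells), sum(complete))
})

test_that("threshold configuration is validated and JSON round-trips", {
  expect_error(als_thresholds(rq_cut = -1), "positive")
  expect_warning(als_thresholds(bmm_bmi_reference = 21), "pivot")
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(hypermetabolism_cut = 40, ldl_cut = 110),
                       cfg, auto_unbox = TRUE)
  th <- read_thresholds(cfg)
  expect_equal(th$hypermetabolism_cut, 40)
  expect_equal(th$ldl_cut, 110)
  expect_equal(th$rq_cut, 0.85)
  jsonlite::write_json(list(nonsense = 1), cfg, auto_unbox = TRUE)
  expect_error(read_thresholds(cfg), "unknown threshold")
})
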