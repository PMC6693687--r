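coef_fixture <- generate_coefficient_fixture(seed = 42L)

test_that("coefficient loading validates the grid and names missing cells", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(coef_fixture, csv)
  expect_silent(load_coefficients(csv))

  holed <- coef_fixture[
    !(coef_fixture$sex == "female" & coef_fixture$site == "lung" &
      coef_fixture$age == 30),
  ]
  csv2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(holed, csv2)
  err <- expect_error(load_coefficients(csv2), class = "ctdoserisk_schema_error")
  expect_match(conditionMessage(err), "female")
  expect_match(conditionMessage(err), "lung")
  expect_match(conditionMessage(err), "30")

  alien <- coef_fixture
  alien$site[1] <- "spleen"
  csv3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(alien, csv3)
  expect_error(load_coefficients(csv3), class = "ctdoserisk_schema_error")
})

test_that("the vendored incidence table loads and is plausible", {
  co <- beir_coefficients()
  expect_setequal(unique(co$age), c(0, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80))
  expect_true(all(co$coefficient >= 0))
  # all-solid male aggregate at 0.1 Gy is of order 10^2-10^3 cases
  solid30 <- sum(co$coefficient[
    co$sex == "male" & co$age == 30 & co$site != "leukaemia"
  ])
  expect_gt(solid30, 300)
  expect_lt(solid30, 3000)
})

test_that("interpolation is exact at knots and linear between them", {
  co <- coef_fixture
  v30 <- co$coefficient[co$sex == "male" & co$site == "colon" & co$age == 30]
  expect_equal(interpolate_coefficient(co, "male", "colon", 30), v30)
  v20 <- co$coefficient[co$sex == "male" & co$site == "colon" & co$age == 20]
  expect_equal(interpolate_coefficient(co, "male", "colon", 25), (v20 + v30) / 2)
  # independent two-point oracle across the whole working range
  for (sx in c("male", "female")) {
    rows <- co[co$sex == sx & co$site == "bladder", ]
    got <- interpolate_coefficient(co, sx, "bladder", 18:80)
    want <- vapply(
      18:80, function(a) interp_oracle(rows$age, rows$coefficient, a),
      numeric(1)
    )
    expect_equal(got, want)
  }
  # second differences vanish inside each knot segment on a yearly grid
  vals <- interpolate_coefficient(coef_fixture, "male", "stomach", 31:39)
  expect_equal(diff(vals, differences = 2), rep(0, 7))
  expect_error(
    interpolate_coefficient(co, "male", "colon", 81),
    class = "ctdoserisk_domain_error"
  )
  expect_error(
    interpolate_coefficient(co, "male", "nonsite", 30),
    class = "ctdoserisk_missing_cell"
  )
})

test_that("a unit exposure at a knot age returns the tabulated coefficient", {
  doses <- tibble::tibble(
    site = cancer_sites("male"),
    dose_msv = ifelse(cancer_sites("male") == "colon", 100, 0)
  )
  lar <- lar_single_exposure(doses, coef_fixture, "male", 40)
  v40 <- coef_fixture$coefficient[
    coef_fixture$sex == "male" & coef_fixture$site == "colon" &
      coef_fixture$age == 40
  ]
  expect_equal(lar$lar_per_100k[lar$site == "colon"], v40)
  expect_equal(sum(lar$lar_per_100k), v40)
  zero <- lar_single_exposure(
    dplyr::mutate(doses, dose_msv = 0), coef_fixture, "male", 40
  )
  expect_equal(sum(zero$lar_per_100k), 0)
})

test_that("risk projection is linear in dose and conserves the total", {
  doses <- tibble::tibble(
    site = cancer_sites("female"), dose_msv = seq_along(cancer_sites("female"))
  )
  c1 <- lar_curve(doses, coef_fixture, "female")
  c2 <- lar_curve(dplyr::mutate(doses, dose_msv = 2 * dose_msv),
    coef_fixture, "female"
  )
  expect_equal(c2$lar_per_100k, 2 * c1$lar_per_100k)
  # conservation at every age
  totals <- lar_total(c1)
  by_age <- tapply(c1$lar_per_100k, c1$age, sum)
  expect_equal(unname(totals$total), unname(as.numeric(by_age)))
  # monotone coefficients + fixed doses => monotone total curve
  expect_true(all(diff(totals$total) < 0))
})

test_that("sex-inapplicable sites never enter a curve", {
  doses <- tibble::tibble(site = cancer_sites(), dose_msv = 5)
  male <- lar_curve(doses, coef_fixture, "male")
  expect_false(any(c("breast", "uterus", "ovary") %in% male$site))
  female <- lar_curve(doses, coef_fixture, "female")
  expect_false("prostate" %in% female$site)
})

test_that("a missing coefficient site is a named error", {
  doses <- tibble::tibble(site = c("colon", "lung"), dose_msv = c(5, 5))
  no_lung <- coef_fixture[coef_fixture$site != "lung", ]
  err <- expect_error(
    lar_curve(doses, no_lung, "male"),
    class = "ctdoserisk_missing_cell"
  )
  expect_match(conditionMessage(err), "lung")
})

test_that("identical curves give zero disparity; axes must match", {
  doses <- tibble::tibble(site = cancer_sites("male"), dose_msv = 3)
  cv <- lar_curve(doses, coef_fixture, "male")
  d <- pct_higher_curve(cv, cv)
  expect_equal(d$pct_higher, rep(0, 63))
  short <- lar_curve(doses, coef_fixture, "male", ages = 18:50)
  expect_error(pct_higher_curve(cv, short), class = "ctdoserisk_domain_error")
})

test_that("with flat coefficients the disparity is the dose-sum difference", {
  flat <- coef_fixture
  flat$coefficient <- 100
  dose_i <- tibble::tibble(site = cancer_sites("male"), dose_msv = 2 + seq_len(9))
  dose_n <- tibble::tibble(site = cancer_sites("male"), dose_msv = 3 + seq_len(9))
  ci <- lar_curve(dose_i, flat, "male")
  cn <- lar_curve(dose_n, flat, "male")
  d <- pct_higher_curve(cn, ci)
  expect_equal(
    d$pct_higher,
    rep(pct_difference(sum(dose_i$dose_msv), sum(dose_n$dose_msv)), 63)
  )
})

test_that("site contributions sum to 100 and isolate single-site curves", {
  doses <- withr::with_seed(
    5, tibble::tibble(site = cancer_sites("male"), dose_msv = runif(9, 1, 10))
  )
  cv <- lar_curve(doses, coef_fixture, "male")
  contrib <- site_contributions(cv)
  expect_equal(sum(contrib$pct), 100, tolerance = 1e-9)
  yearly <- site_contributions(cv, weighting = "yearly_mean")
  expect_equal(sum(yearly$pct), 100, tolerance = 1e-9)
  solo <- lar_curve(
    tibble::tibble(site = "liver", dose_msv = 4), coef_fixture, "male"
  )
  expect_equal(site_contributions(solo)$pct, 100)
  zero <- lar_curve(
    tibble::tibble(site = "liver", dose_msv = 0), coef_fixture, "male"
  )
  expect_error(site_contributions(zero), class = "ctdoserisk_degenerate")
})

test_that("head-protocol curves are dominated by marrow and remainder doses", {
  tab <- study_median_doses()
  co <- beir_coefficients()
  cv <- lar_curve(tab, co, "male", protocol = "head", software = "impact")
  contrib <- site_contributions(cv)
  top2 <- contrib$site[1:2]
  expect_setequal(top2, c("other", "leukaemia"))
  expect_gt(sum(contrib$pct[contrib$site %in% top2]), 95)
})
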