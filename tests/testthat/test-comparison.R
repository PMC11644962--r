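test_that("profile alignment interpolates onto the sparse grid", {
  auto <- zone_profile(1:600, 25 + 0.001 * (1:600), "RSM", "automatic")
  semi <- zone_profile(seq(30, 600, 30), rep(0, 20), "Rmax",
                       "semi_automatic_max")
  pair <- align_profiles(auto, semi)
  expect_equal(nrow(pair), 20)
  # a linear automatic series interpolates exactly onto the line
  expect_equal(pair$b, 25 + 0.001 * seq(30, 600, 30), tolerance = 1e-12)
  # identical grids: interpolation is the identity
  semi2 <- zone_profile(1:10, rnorm(10), "Rmax", "semi_automatic_max")
  auto2 <- zone_profile(1:10, rnorm(10, 30), "RSM", "automatic")
  expect_equal(align_profiles(auto2, semi2)$b, auto2$temp_c)
  # points outside coverage are dropped and counted
  semi3 <- zone_profile(c(0.1, 1:9, 11), rnorm(11), "Rmax",
                        "semi_automatic_max")
  p3 <- align_profiles(auto2, semi3)
  expect_equal(attr(p3, "n_dropped"), 2L)
  expect_equal(nrow(p3), 9)
  # too little overlap errors
  semi4 <- zone_profile(c(20, 21, 22), 1:3, "Rmax", "semi_automatic_max")
  expect_error(align_profiles(auto2, semi4), "3 overlapping")
})

test_that("linear fit matches the closed-form OLS oracle", {
  pair <- function(a, b) {
    d <- data.frame(t_s = seq_along(a), a = a, b = b)
    class(d) <- c("paired_series", "data.frame"); d
  }
  f1 <- fit_linear(pair(1:10, 1:10))
  expect_equal(f1$slope, 1); expect_equal(f1$intercept, 0)
  expect_equal(f1$r2, 1)
  f2 <- fit_linear(pair(1:10, 2 * (1:10) + 1))
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1)
  expect_equal(f2$r2, 1)
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(20, 30, 2)
    b <- 0.8 * a + rnorm(20, 0, 0.5)
    got <- fit_linear(pair(a, b))
    want <- oracle_ols(a, b)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
    # R^2 invariant under affine rescaling of b
    got2 <- fit_linear(pair(a, 3 * b - 7))
    expect_equal(got2$r2, got$r2, tolerance = 1e-10)
  }
  expect_error(fit_linear(pair(rep(1, 5), rnorm(5))), "variance")
})

test_that("RMSE about the trend recovers residual noise scale", {
  lin <- zone_profile(1:100, 20 + 0.01 * (1:100), "RSM", "automatic")
  expect_equal(rmse_vs_trend(lin), 0, tolerance = 1e-10)
  const <- zone_profile(1:100, rep(20, 100), "RP", "automatic")
  expect_equal(rmse_vs_trend(const), 0, tolerance = 1e-12)
  set.seed(8)
  noisy <- zone_profile(1:600, 20 + 0.01 * (1:600) + rnorm(600, 0, 0.1),
                        "RSM", "automatic")
  expect_equal(rmse_vs_trend(noisy), 0.1, tolerance = 0.1)
})

test_that("Bland-Altman matches direct arithmetic and swap negates", {
  pair <- function(a, b) {
    d <- data.frame(a = a, b = b)
    class(d) <- c("paired_series", "data.frame"); d
  }
  ba0 <- bland_altman(pair(1:10, 1:10))
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd_diff, 0)
  ba1 <- bland_altman(pair(1:10, (1:10) + 0.3))
  expect_equal(ba1$bias, 0.3)
  expect_equal(ba1$loa_low, 0.3); expect_equal(ba1$loa_high, 0.3)
  set.seed(12)
  for (i in 1:50) {
    a <- rnorm(15, 30); b <- a + rnorm(15, 0.2, 0.3)
    got <- bland_altman(pair(a, b))
    want <- oracle_bland_altman(a, b)
    expect_equal(got$bias, want$bias, tolerance = 1e-10)
    expect_equal(got$loa_low, want$loa_low, tolerance = 1e-10)
    expect_equal(got$loa_high, want$loa_high, tolerance = 1e-10)
    # swapping a and b negates bias and mirrors the limits
    sw <- bland_altman(pair(b, a))
    expect_equal(sw$bias, -got$bias, tolerance = 1e-12)
    expect_equal(sw$loa_low, -got$loa_high, tolerance = 1e-12)
    expect_equal(sw$loa_high, -got$loa_low, tolerance = 1e-12)
  }
})

test_that("agreement classification truth table and symmetry", {
  expect_equal(classify_agreement(TRUE, TRUE), "AG")
  expect_equal(classify_agreement(FALSE, FALSE), "NAG")
  expect_equal(classify_agreement(TRUE, FALSE), "PAG")
  expect_equal(classify_agreement(FALSE, TRUE), "PAG")
  expect_true(is.na(classify_agreement(NA, TRUE)))
  for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE))
    expect_equal(classify_agreement(x, y), classify_agreement(y, x))
})

test_that("thermally responsive leg is matched to the heavier leg", {
  t <- 1:100
  warm <- function(s) zone_profile(t, 25 + s * t / 60, "SM", "automatic")
  m <- leg_thermal_match(warm(0.10), warm(0.05), "left", "heating_SM")
  expect_true(m$match); expect_equal(m$responsive_leg, "left")
  m2 <- leg_thermal_match(warm(0.10), warm(0.05), "right", "heating_SM")
  expect_false(m2$match)
  cool <- function(s) zone_profile(t, 25 - s * t / 60, "P", "automatic")
  m3 <- leg_thermal_match(cool(0.08), cool(0.03), "left", "cooling_P")
  expect_true(m3$match)   # larger-magnitude cooling on the left
  # identical profiles: indeterminate tie, excluded with a warning
  expect_warning(m4 <- leg_thermal_match(warm(0.1), warm(0.1), "left"),
                 "tie")
  expect_true(is.na(m4$match))
})

test_that("stratification reproduces an independent group-by aggregation", {
  m <- data.frame(participant = "P1", gender = c("F", "F"), bmi = 22,
                  asymmetric = TRUE, r2 = c(0.6, 0.8), strong = TRUE)
  st <- stratify_results(m)
  w <- st$r2_table[st$r2_table$group == "W", ]
  expect_equal(w$r2_mean, 0.7)
  expect_equal(w$r2_sd, sd(c(0.6, 0.8)), tolerance = 1e-12)
  # single-member group: sd undefined
  m1 <- m[1, ]
  st1 <- stratify_results(m1)
  expect_true(is.na(st1$r2_table$r2_sd[st1$r2_table$group == "W"]))
  # empty groups absent, not zero
  expect_false("M" %in% st1$r2_table$group)
  # random cohort vs tapply oracle
  set.seed(77)
  mc <- data.frame(
    participant = rep(sprintf("P%02d", 1:20), each = 4),
    gender = rep(sample(c("M", "F"), 20, replace = TRUE), each = 4),
    bmi = rep(runif(20, 18, 32), each = 4),
    asymmetric = rep(runif(20) < 0.5, each = 4),
    r2 = runif(80), strong = runif(80) < 0.7)
  st2 <- stratify_results(mc, bmi_cutoff = 25)
  sel <- mc$strong & mc$gender == "M"
  expect_equal(st2$r2_table$r2_mean[st2$r2_table$group == "M"],
               mean(mc$r2[sel]), tolerance = 1e-12)
  sel2 <- mc$strong & mc$bmi < 25
  expect_equal(st2$r2_table$r2_mean[st2$r2_table$group == "bmi_low"],
               mean(mc$r2[sel2]), tolerance = 1e-12)
  # label counts per gender
  lab <- data.frame(participant = sprintf("P%02d", 1:6),
                    gender = c("M", "M", "M", "F", "F", "F"),
                    label_heating = c("AG", "AG", "PAG", "NAG", "AG", "PAG"),
                    label_cooling = c("AG", "NAG", "NAG", "AG", "PAG", "AG"))
  st3 <- stratify_results(mc, labels = lab)
  h <- st3$label_counts$heating
  expect_equal(h$count[h$gender == "M" & h$label == "AG"], 2)
  expect_equal(h$count[h$gender == "F" & h$label == "NAG"], 1)
})
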