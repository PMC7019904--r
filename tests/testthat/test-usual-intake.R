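test_that("variance decomposition matches the one-way ANOVA oracle on balanced data", {
  sim <- balanced_intake_data(300,
    lambda = 1, beta0 = 10, sd_between = 1.2,
    sd_within = 0.6, seed = 4, weekend = FALSE
  )
  m <- fit_usual_intake(sim$data, lambda = 1, covariates = character(0))
  # method-of-moments oracle: with 2 days/person, var_within = MS within,
  # var_between = (MS between - MS within) / 2
  z <- sim$data$amount - 1 # lambda = 1 transform
  zm <- matrix(z, ncol = 2)
  person_mean <- rowMeans(zm)
  msw <- sum((zm - person_mean)^2) / nrow(zm)
  msb <- 2 * sum((person_mean - mean(z))^2) / (nrow(zm) - 1)
  expect_equal(m$var_within, msw, tolerance = 1e-6)
  expect_equal(m$var_between, (msb - msw) / 2, tolerance = 1e-6)
  expect_equal(unname(m$beta[["(Intercept)"]]), mean(z), tolerance = 1e-6)
})

test_that("zero within-person variance collapses onto the between-person split", {
  sim <- balanced_intake_data(150,
    lambda = 1, sd_between = 2, sd_within = 0,
    seed = 5, weekend = FALSE
  )
  m <- suppressWarnings(
    fit_usual_intake(sim$data, lambda = 1, covariates = character(0))
  )
  expect_lt(m$var_within, 1e-8)
  z <- sim$data$amount - 1
  expect_equal(m$var_between, var(z[1:150]), tolerance = 1e-4)
})

test_that("a weekend effect on the transformed scale is recovered", {
  sim <- balanced_intake_data(2000,
    lambda = 0.5, beta0 = 8, beta_weekend = 0.3,
    sd_between = 0.8, sd_within = 0.5, seed = 6
  )
  m <- fit_usual_intake(sim$data, lambda = 0.5)
  expect_lt(abs(unname(m$beta[["weekendTRUE"]]) - 0.3), 0.05)
})

test_that("a collinear covariate is reported by name", {
  sim <- balanced_intake_data(50, seed = 7, weekend = FALSE)
  sim$data$shadow <- as.numeric(sim$data$weekend) # constant duplicate
  expect_error(
    fit_usual_intake(sim$data,
      lambda = 1,
      covariates = c("weekend", "shadow")
    ),
    "collinear"
  )
})

test_that("identity-transform back-transformation is exact and linear in b", {
  sim <- balanced_intake_data(80,
    lambda = 1, beta0 = 10, sd_between = 1,
    sd_within = 0.7, seed = 8, weekend = FALSE
  )
  m <- fit_usual_intake(sim$data, lambda = 1, covariates = character(0))
  mu <- unname(m$beta[["(Intercept)"]])
  # with lambda = 1 the within-person error integrates out exactly:
  # E[(mu + b + eps) + 1] = mu + b + 1, whatever var_within is
  for (b in c(-2, 0, 1.5)) {
    expect_equal(usual_intake_of_person(m, b = b), mu + b + 1,
      tolerance = 1e-10
    )
  }
})

test_that("Gauss-Hermite back-transformation matches a brute-force Monte Carlo oracle", {
  m <- structure(
    list(
      nutrient = NULL, lambda = 0.5, beta = c("(Intercept)" = 4),
      var_between = 0.4, var_within = 0.36, offset = 0,
      covariates = character(0), age_levels = NULL,
      n_persons = 1, n_days = 2, fit = NULL, call = NULL
    ),
    class = "usual_intake"
  )
  b <- 0.3
  got <- usual_intake_of_person(m, b = b, weekend = "weekday")
  set.seed(99)
  eps <- rnorm(1e6, 0, sqrt(m$var_within))
  oracle <- mean(boxcox_inverse(4 + b + eps, 0.5))
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("simulated distributions are reproducible and stable in n_mc", {
  sim <- balanced_intake_data(200,
    lambda = 0.5, beta0 = 6, sd_between = 0.6,
    sd_within = 0.5, seed = 9
  )
  m <- fit_usual_intake(sim$data, lambda = 0.5)
  persons <- data.frame(
    person_id = unique(sim$data$person_id),
    weight = rlnorm(200, 10, 0.3)
  )
  d1 <- simulate(m, nsim = 50, seed = 123, persons = persons)
  d2 <- simulate(m, nsim = 50, seed = 123, persons = persons)
  expect_identical(d1, d2)
  expect_true(all(d1$usual_intake > 0))
  expect_equal(sum(d1$weight), sum(persons$weight), tolerance = 1e-9)
  # doubling the Monte Carlo size moves the weighted mean only by MC noise
  d4 <- simulate(m, nsim = 100, seed = 124, persons = persons)
  expect_equal(mean_ui(d1), mean_ui(d4), tolerance = 0.02)
  # no between-person variance: all pseudo-persons of a profile coincide
  m0 <- m
  m0$var_between <- 0
  d0 <- simulate(m0, nsim = 10, seed = 1, persons = persons)
  expect_equal(length(unique(round(d0$usual_intake, 12))), 1L)
})

test_that("cut-point prevalences respect their boundary conventions", {
  dist <- data.frame(
    person_id = c("p1", "p2", "p3", "p4"),
    usual_intake = c(5, 10, 15, 20),
    weight = c(1, 1, 1, 1)
  )
  attr(dist, "nutrient") <- "vit_d"
  demo <- data.frame(
    person_id = c("p1", "p2", "p3", "p4"),
    sex = "F", age_years = 30
  )
  dri <- dri_table(data.frame(
    nutrient = "vit_d", sex = c("F", "M"), age_min = 0, age_max = 200,
    ear = 10, ul = 20
  ))
  # strictly below the EAR: intake exactly at 10 does not count
  expect_equal(prev_below_ear(dist, dri, demo), 25)
  # at or above the UL: intake exactly at 20 counts
  expect_equal(prev_at_or_above_ul(dist, dri, demo), 25)
  # all intakes above every EAR gives zero inadequacy
  dri_lo <- dri_table(data.frame(
    nutrient = "vit_d", sex = c("F", "M"), age_min = 0, age_max = 200,
    ear = 1, ul = 1000
  ))
  expect_equal(prev_below_ear(dist, dri_lo, demo), 0)
  # no UL established: explicit NA, never zero
  dri_noul <- dri_table(data.frame(
    nutrient = "vit_d", sex = c("F", "M"), age_min = 0, age_max = 200,
    ear = 10, ul = NA_real_
  ))
  expect_true(is.na(prev_at_or_above_ul(dist, dri_noul, demo)))
  # unmapped demographic group errors
  demo_bad <- demo
  demo_bad$age_years[1] <- 300
  dri_gap <- dri_table(data.frame(
    nutrient = "vit_d", sex = c("F", "M"), age_min = 0, age_max = 200,
    ear = 10, ul = 20
  ))
  expect_error(prev_below_ear(dist, dri_gap, demo_bad), "no DRI group")
})

test_that("the shipped adult DRI reference parses with age-sex lookup intact", {
  path <- system.file("extdata", "dri_adults.csv", package = "fortiscope")
  dri <- read_dri(path)
  expect_s3_class(dri, "dri_table")
  demo <- data.frame(
    person_id = c("a", "b"), sex = c("F", "M"), age_years = c(60, 25)
  )
  ear <- fortiscope:::dri_for_persons(dri, demo, "calcium", "ear")
  expect_equal(unname(ear), c(1000, 800))
  # empty UL cells read as not-established
  ul <- fortiscope:::dri_for_persons(dri, demo, "vit_b12", "ul")
  expect_true(all(is.na(ul)))
})

test_that("a Gaussian usual-intake distribution recovers a known EAR percentile", {
  set.seed(11)
  n <- 20000
  dist <- data.frame(
    person_id = sprintf("p%05d", seq_len(n)),
    usual_intake = rnorm(n, 100, 10),
    weight = 1
  )
  demo <- data.frame(person_id = dist$person_id, sex = "M", age_years = 40)
  ear <- qnorm(0.30, 100, 10) # EAR at the 30th percentile
  dri <- dri_table(data.frame(
    nutrient = "calcium", sex = c("M", "F"), age_min = 0, age_max = 200,
    ear = ear, ul = NA_real_
  ))
  expect_equal(prev_below_ear(dist, dri, demo, nutrient = "calcium"), 30,
    tolerance = 0.03
  )
})

test_that("the model object supports the standard accessor methods", {
  sim <- balanced_intake_data(60, lambda = 0.5, seed = 12)
  m <- fit_usual_intake(sim$data, lambda = 0.5, nutrient = "vit_c")
  expect_named(coef(m), names(m$beta))
  expect_length(residuals(m), nrow(sim$data))
  expect_output(print(m), "Box-Cox lambda")
  expect_output(print(summary(m)), "intraclass")
})
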