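#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic food database and population
#' generator, with defaults chosen to resemble a two-day national
#' dietary survey merged with a source-partitioned food composition
#' database: 200 foods, 500 persons in a 16-stratum / 2-PSU design,
#' daily intakes lognormal-like (Box-Cox exponent 0.35) with
#' between-person CV 25% and within-person day-to-day CV 40%, a +10%
#' weekend effect, a -5% second-interview effect, and mild age-group
#' differences. Fortified foods are pinned at discrete percent-DV
#' targets (10/25/50/100% of the current DV per RACC) so claim counts
#' and rewrite behavior have exact combinatorial oracles, with targets
#' straddling the fortification-zeroing boundary by construction.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_persons = 50, nutrients = "vit_d")
generator_config <- function(...) {
  cfg <- list(
    nutrients = all_nutrients(),
    n_foods = 200,
    n_persons = 500,
    n_strata = 16,
    seed = 20201L,
    # food database
    fraction_fortified = 0.25,
    fraction_enriched = 0.30,
    fortified_pdv_targets = c(10, 25, 50, 100),
    intrinsic_pdv_median = 8,
    intrinsic_sdlog = 0.6,
    racc_choices = c(30, 55, 85, 120, 240),
    # person-level intake model (per nutrient, transformed scale)
    lambda = 0.35,
    cv_between = 0.25,
    cv_within = 0.40,
    weekend_mult = 0.10,
    day2_mult = -0.05,
    age_mult = c("19-30" = 0, "31-50" = -0.03, "51-70" = -0.05, "70+" = -0.10),
    median_intake_dv_frac = 0.8,
    foods_per_day = 3,
    # roster composition (exclusion-path fractions)
    frac_incomplete = 0.03,
    frac_pregnant = 0.02,
    frac_minor = 0.05,
    # reference values without an established UL
    no_ul = c("vit_b12", "thiamin", "riboflavin"),
    dv = NULL # calibration DV table; dv_current() when NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown generator option(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(dots)] <- dots
  if (is.null(cfg$dv)) cfg$dv <- dv_current()
  check_nutrient(cfg$nutrients)
  stopifnot(
    cfg$fraction_fortified >= 0, cfg$fraction_fortified <= 1,
    cfg$fraction_enriched >= 0, cfg$fraction_enriched <= 1,
    cfg$cv_between >= 0, cfg$cv_within > 0,
    cfg$lambda > 0, cfg$lambda <= 1
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Assign adult age groups
#'
#' @param age_years Numeric ages.
#' @return Factor with levels `19-30`, `31-50`, `51-70`, `70+` (NA below
#'   19).
#' @export
age_group_of <- function(age_years) {
  cut(age_years,
    breaks = c(19, 31, 51, 71, Inf),
    labels = c("19-30", "31-50", "51-70", "70+"),
    right = FALSE
  )
}

#' Generate a synthetic source-partitioned food database
#'
#' Foods are distributed round-robin over the configured nutrients, each
#' food carrying exactly one nutrient (a deliberate simplification that
#' makes exact intake allocation feasible; see the methods vignette).
#' Non-fortified foods get a lognormal intrinsic amount (median
#' `intrinsic_pdv_median` percent of DV per RACC) and, with probability
#' `fraction_enriched`, an enrichment component. Fortified foods are
#' constructed backwards from a percent-DV target drawn from
#' `fortified_pdv_targets`: the total per RACC equals exactly
#' `target/100 * DV`, split into intrinsic (10-50%), optional enriched,
#' and the fortified remainder.
#'
#' @param config A [generator_config()].
#' @return A [food_db()] whose entries carry an extra `pdv_target` column
#'   (NA for non-fortified foods) for oracle checks.
#' @export
generate_food_db <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_foods
  nutr <- rep_len(config$nutrients, n)
  dv <- config$dv

  racc <- sample(config$racc_choices, n, replace = TRUE)
  fortified <- stats::runif(n) < config$fraction_fortified
  enriched <- stats::runif(n) < config$fraction_enriched
  pdv_target <- rep(NA_real_, n)

  I <- E <- FF <- numeric(n)
  for (i in seq_len(n)) {
    dvn <- dv_lookup(dv, nutr[i])
    if (fortified[i]) {
      targets <- config$fortified_pdv_targets
      pdv_target[i] <- targets[sample.int(length(targets), 1)]
      total <- pdv_target[i] / 100 * dvn
      I[i] <- stats::runif(1, 0.1, 0.5) * total
      rest <- total - I[i]
      E[i] <- if (enriched[i]) stats::runif(1, 0.2, 0.5) * rest else 0
      FF[i] <- total - I[i] - E[i]
    } else {
      I[i] <- config$intrinsic_pdv_median / 100 * dvn *
        stats::rlnorm(1, 0, config$intrinsic_sdlog)
      E[i] <- if (enriched[i]) stats::runif(1, 0.05, 0.15) * dvn else 0
    }
  }
  total_racc <- I + E + FF
  entries <- data.frame(
    food_id = sprintf("f%04d", seq_len(n)),
    food_desc = paste0("synthetic food ", seq_len(n), " (", nutr, ")"),
    nutrient = nutr,
    total_per_100g = total_racc * 100 / racc,
    pct_intrinsic = 100 * I / total_racc,
    pct_enriched = 100 * E / total_racc,
    pct_fortified = 100 * FF / total_racc,
    racc_g = racc,
    pdv_target = pdv_target,
    stringsAsFactors = FALSE
  )
  food_db(entries, label = "Original")
}

# per-nutrient true model parameters implied by a config
true_params <- function(config, nutrient) {
  m <- config$median_intake_dv_frac * dv_lookup(config$dv, nutrient)
  s <- m^config$lambda # transformed-scale unit from delta method
  list(
    lambda = config$lambda,
    beta0 = boxcox_transform(m, config$lambda),
    beta_weekend = config$weekend_mult * s,
    beta_day2 = config$day2_mult * s,
    beta_age = config$age_mult * s,
    sd_between = config$cv_between * s,
    sd_within = config$cv_within * s
  )
}

# analytic usual intake from the generator's own parameters:
# weekend-balanced (4/7, 3/7), day-1 level, dense Gauss-Hermite
true_usual_intake <- function(p, age_group, b, gh = pracma::gaussHermite(41)) {
  mu_base <- p$beta0 + unname(p$beta_age[as.character(age_group)])
  ev <- function(mu) {
    acc <- 0
    for (k in seq_along(gh$x)) {
      acc <- acc + gh$w[k] *
        boxcox_inverse(mu + b + sqrt(2) * p$sd_within * gh$x[k], p$lambda)
    }
    acc / sqrt(pi)
  }
  4 / 7 * ev(mu_base) + 3 / 7 * ev(mu_base + p$beta_weekend)
}

#' Generate a synthetic survey population with two-day recalls
#'
#' Draws a roster (ages, sexes, pregnancy flags, lognormal survey
#' weights, a 2-PSU-per-stratum design), per-person random effects and
#' per-day residuals on the transformed scale, realizes each person-day
#' total intake per nutrient through the Box-Cox inverse, and allocates
#' it in grams across a personal repertoire of foods carrying that
#' nutrient so that [merge_recalls()] reproduces the intended totals
#' exactly. Weekend flags are drawn with probability 3/7. The analytic
#' truth (per-person usual intakes and the generating parameters) is
#' returned alongside the data for recovery testing.
#'
#' @param config A [generator_config()].
#' @param fd The food database from [generate_food_db()].
#' @return list with `persons`, `recalls`, `design`, `truth` (data.frame
#'   `person_id`, `nutrient`, `true_ui`, `b`), `day_totals` (intended
#'   person-day totals), and `params` (per-nutrient true parameters).
#' @export
generate_population_and_recalls <- function(config, fd) {
  stopifnot(inherits(config, "generator_config"), inherits(fd, "food_db"))
  set.seed(config$seed + 1L)
  np <- config$n_persons

  n_minor <- round(config$frac_minor * np)
  age <- c(
    sample(4:18, n_minor, replace = TRUE),
    sample(19:85, np - n_minor, replace = TRUE)
  )
  sex <- sample(c("M", "F"), np, replace = TRUE)
  preg <- rep(FALSE, np)
  adult_f <- which(sex == "F" & age >= 19 & age <= 49)
  n_preg <- min(length(adult_f), round(config$frac_pregnant * np))
  if (n_preg > 0) preg[sample(adult_f, n_preg)] <- TRUE

  stratum <- rep_len(sprintf("s%02d", seq_len(config$n_strata)), np)
  psu <- rep_len(rep(1:2, each = config$n_strata), np)
  persons <- data.frame(
    person_id = sprintf("p%04d", seq_len(np)),
    age_years = age,
    sex = sex,
    pregnant_or_lactating = preg,
    weight = stats::rlnorm(np, log(20000), 0.3),
    stratum_id = stratum,
    psu_id = psu,
    stringsAsFactors = FALSE
  )
  persons$age_group <- age_group_of(persons$age_years)

  incomplete <- stats::runif(np) < config$frac_incomplete
  weekend <- matrix(stats::runif(np * 2) < 3 / 7, nrow = np, ncol = 2)

  nutrients <- config$nutrients
  params <- lapply(nutrients, function(n) true_params(config, n))
  names(params) <- nutrients
  food_lists <- split(seq_len(nrow(fd)), fd$nutrient)

  # age effects reference level "19-30"; minors borrow it (excluded later)
  ag <- as.character(persons$age_group)
  ag[is.na(ag)] <- "19-30"

  recall_list <- list()
  truth_list <- list()
  totals_list <- list()
  for (n in nutrients) {
    p <- params[[n]]
    b <- stats::rnorm(np, 0, p$sd_between)
    eps <- matrix(stats::rnorm(np * 2, 0, p$sd_within), nrow = np)
    idx_foods <- food_lists[[n]]
    if (is.null(idx_foods) || !length(idx_foods)) {
      stop("no foods carry nutrient ", n, call. = FALSE)
    }
    k <- min(config$foods_per_day, length(idx_foods))
    # personal food repertoire: stable across days so fortification
    # exposure is a person-level trait
    repertoire <- lapply(seq_len(np), function(i) {
      sample(idx_foods, k, replace = FALSE)
    })
    per100 <- fd$total_per_100g

    for (d in 1:2) {
      mu <- p$beta0 +
        p$beta_weekend * weekend[, d] +
        p$beta_day2 * (d == 2) +
        unname(p$beta_age[ag]) +
        b + eps[, d]
      total <- boxcox_inverse(mu, p$lambda)
      props <- matrix(stats::rgamma(np * k, shape = 1), nrow = np)
      props <- props / rowSums(props)
      for (i in seq_len(np)) {
        if (total[i] <= 0) next
        f <- repertoire[[i]]
        grams <- props[i, seq_along(f)] * total[i] / (per100[f] / 100)
        recall_list[[length(recall_list) + 1L]] <- data.frame(
          person_id = persons$person_id[i],
          day = d,
          food_id = fd$food_id[f],
          grams_consumed = grams,
          weekend = weekend[i, d],
          complete = !(incomplete[i] & d == 2L),
          stringsAsFactors = FALSE
        )
      }
      totals_list[[length(totals_list) + 1L]] <- data.frame(
        person_id = persons$person_id,
        day = d,
        nutrient = n,
        total = total,
        stringsAsFactors = FALSE
      )
    }
    truth_list[[length(truth_list) + 1L]] <- data.frame(
      person_id = persons$person_id,
      nutrient = n,
      true_ui = true_usual_intake(p, ag, b),
      b = b,
      stringsAsFactors = FALSE
    )
  }

  recalls <- do.call(rbind, recall_list)
  rownames(recalls) <- NULL
  list(
    persons = persons,
    recalls = recalls,
    design = persons[c("person_id", "stratum_id", "psu_id")],
    truth = do.call(rbind, truth_list),
    day_totals = do.call(rbind, totals_list),
    params = params
  )
}

#' Build a synthetic DRI reference table from generator truth
#'
#' Places each nutrient's EAR and UL at chosen weighted quantiles of the
#' true usual-intake distribution of a reference sample, identically for
#' every age-sex group (the lookup machinery is exercised; the truth
#' stays analytically known). Nutrients in the config's `no_ul` set get
#' no UL.
#'
#' @param truth The `truth` data.frame from
#'   [generate_population_and_recalls()], usually restricted to the
#'   analytic sample.
#' @param persons Roster providing weights for the quantiles.
#' @param ear_quantile,ul_quantile Quantiles of true usual intake at
#'   which to place the EAR and UL.
#' @param no_ul Nutrients with no established UL.
#' @return A [dri_table()].
#' @export
synthetic_dri <- function(truth, persons, ear_quantile = 0.4,
                          ul_quantile = 0.975,
                          no_ul = c("vit_b12", "thiamin", "riboflavin")) {
  rows <- list()
  for (n in unique(truth$nutrient)) {
    sub <- truth[truth$nutrient == n, ]
    w <- persons$weight[match(sub$person_id, persons$person_id)]
    ear <- weighted_quantile(sub$true_ui, w, ear_quantile)
    ul <- if (n %in% no_ul) NA_real_ else {
      weighted_quantile(sub$true_ui, w, ul_quantile)
    }
    for (s in c("M", "F")) {
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = n, sex = s, age_min = 0, age_max = 200,
        ear = ear, ul = ul, stringsAsFactors = FALSE
      )
    }
  }
  dri_table(do.call(rbind, rows))
}

#' Weighted quantile (left-continuous inverse of the weighted ECDF)
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param p Probability in [0, 1].
#' @return The smallest `x` whose cumulative weight share reaches `p`.
#' @export
weighted_quantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), p >= 0, p <= 1)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1L]]
}
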