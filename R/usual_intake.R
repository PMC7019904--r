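#' Fit a usual-intake measurement-error model to repeated 24-h recalls
#'
#' The workhorse estimator of the package: a one-part (amount-only)
#' usual-intake model in the spirit of the NCI method for nutrients
#' consumed nearly every day. Daily amounts are Box-Cox transformed
#' (exponent chosen by profile likelihood on a grid, or fixed by the
#' caller), then modeled with a linear mixed model
#'
#' \deqn{z_{ij} = x_{ij}'\beta + b_i + \epsilon_{ij}, \quad
#'   b_i \sim N(0, \sigma_b^2), \; \epsilon_{ij} \sim N(0, \sigma_w^2)}
#'
#' fitted by REML, where the fixed effects are an intercept, a weekend
#' indicator, an interview-sequence indicator (day 2 vs day 1, a nuisance
#' capturing recall attenuation), and optional age-group terms. The
#' person effect \eqn{b_i} carries between-person variation; the residual
#' carries within-person day-to-day variation, which is integrated out of
#' the back-transformation when usual intake is computed (see
#' [predict.usual_intake()] and [simulate.usual_intake()]).
#'
#' Zero-intake days are handled with a half-minimum offset: half the
#' smallest positive amount is added to all amounts before
#' transformation and removed after back-transformation.
#'
#' @param data Person-day intakes: columns `person_id`, `day` (1 or 2),
#'   `amount` (or `amount_total`), `weekend` (logical), and optionally
#'   `age_group` (factor).
#' @param nutrient Optional nutrient identifier, carried in the object.
#' @param lambda Fix the Box-Cox exponent; `NULL` (default) selects it by
#'   [fit_boxcox_lambda()].
#' @param lambda_grid Grid for the exponent search.
#' @param covariates Fixed-effect columns besides the intercept; defaults
#'   to `weekend` and the day-2 indicator, plus `age_group` when present.
#' @param sample_weights Optional per-row weights entering the mixed fit
#'   as prior weights (used by full-pipeline BRR replication); `NULL` for
#'   the standard unweighted fit.
#' @return Object of class `usual_intake` with components `lambda`,
#'   `beta`, `var_between`, `var_within`, `offset`, `fit` (the underlying
#'   `merMod`), and bookkeeping fields.
#' @seealso [predict.usual_intake()], [simulate.usual_intake()],
#'   [mean_ui()], [prev_below_ear()]
#' @export
fit_usual_intake <- function(data, nutrient = NULL, lambda = NULL,
                             lambda_grid = seq(0.01, 1, by = 0.01),
                             covariates = NULL, sample_weights = NULL) {
  data <- as.data.frame(data)
  if (!is.null(sample_weights)) {
    stopifnot(length(sample_weights) == nrow(data))
    data$.w <- sample_weights
  }
  if (!"amount" %in% names(data) && "amount_total" %in% names(data)) {
    data$amount <- data$amount_total
  }
  stopifnot(all(c("person_id", "day", "amount") %in% names(data)))
  data <- data[is.finite(data$amount), , drop = FALSE]
  if (!nrow(data)) stop("no usable person-day amounts", call. = FALSE)
  if (any(data$amount < 0)) stop("negative daily amounts", call. = FALSE)
  if (all(data$amount == 0)) {
    stop("all daily amounts are zero; nothing to model", call. = FALSE)
  }
  if (!any(table(data$person_id) >= 2)) {
    stop("between-person variance is unidentifiable without repeated days",
      call. = FALSE
    )
  }

  offset <- 0
  if (any(data$amount == 0)) {
    offset <- min(data$amount[data$amount > 0]) / 2
    message(
      "zero-intake days present; applying half-minimum offset ",
      signif(offset, 4)
    )
  }
  y <- data$amount + offset

  if (is.null(lambda)) lambda <- fit_boxcox_lambda(y, grid = lambda_grid)
  z <- boxcox_transform(y, lambda)

  data$day2 <- as.numeric(data$day == 2)
  if (is.null(covariates)) {
    covariates <- intersect(c("weekend", "day2", "age_group"), names(data))
  }
  fixed <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  mf <- data
  mf$.z <- z
  X <- stats::model.matrix(
    stats::as.formula(paste("~", fixed)),
    mf
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(
      "singular fixed-effect design; collinear term(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  # center and scale the response for the optimizer; exact to undo
  z_center <- mean(z)
  z_scale <- stats::sd(z)
  if (!is.finite(z_scale) || z_scale == 0) z_scale <- 1
  mf$.z <- (z - z_center) / z_scale

  # degeneracy probe: pooled day-to-day variance of the OLS residuals.
  # With (numerically) no within-person variation the REML profile is
  # ill-posed (unbounded likelihood on the singular boundary), so the
  # mixed fit is replaced by OLS betas plus moment variance estimators.
  ols <- stats::lm.fit(X, mf$.z)
  moment_split <- function(r) {
    pm <- tapply(r, data$person_id, mean)
    pv <- tapply(r, data$person_id, function(x) {
      if (length(x) > 1) stats::var(x) else NA_real_
    })
    vw <- mean(pv, na.rm = TRUE)
    ndays <- mean(table(data$person_id))
    list(within = vw, between = max(0, stats::var(pm) - vw / ndays))
  }
  probe <- moment_split(ols$residuals)
  if (probe$within < 1e-10 * (probe$within + probe$between)) {
    beta <- ols$coefficients
    var_within <- probe$within
    var_between <- probe$between
    fit <- NULL
  } else {
    form <- stats::as.formula(paste(".z ~", fixed, "+ (1 | person_id)"))
    fit <- if (is.null(sample_weights)) {
      lme4::lmer(form, data = mf, REML = TRUE)
    } else {
      lme4::lmer(form, data = mf, REML = TRUE, weights = mf$.w)
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_between <- vc$vcov[vc$grp == "person_id"]
    var_within <- vc$vcov[vc$grp == "Residual"]
    beta <- lme4::fixef(fit)
  }

  # undo the standardization
  beta <- beta * z_scale
  beta[["(Intercept)"]] <- beta[["(Intercept)"]] + z_center
  var_between <- var_between * z_scale^2
  var_within <- var_within * z_scale^2

  age_levels <- if ("age_group" %in% covariates) {
    levels(factor(data$age_group))
  } else {
    NULL
  }
  structure(
    list(
      nutrient = nutrient,
      lambda = lambda,
      beta = beta,
      var_between = var_between,
      var_within = var_within,
      offset = offset,
      z_scale = z_scale,
      covariates = covariates,
      age_levels = age_levels,
      n_persons = length(unique(data$person_id)),
      n_days = nrow(data),
      fit = fit,
      resid = if (is.null(fit)) unname(ols$residuals) * z_scale else NULL,
      call = match.call()
    ),
    class = "usual_intake"
  )
}

#' @export
print.usual_intake <- function(x, ...) {
  cat("Usual-intake measurement-error model",
    if (!is.null(x$nutrient)) paste0("(", x$nutrient, ")"), "\n"
  )
  cat(sprintf(
    "  %d persons, %d person-days; Box-Cox lambda = %.2f\n",
    x$n_persons, x$n_days, x$lambda
  ))
  cat(sprintf(
    "  var between = %.4g, var within = %.4g (transformed scale)\n",
    x$var_between, x$var_within
  ))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
summary.usual_intake <- function(object, ...) {
  icc <- object$var_between / (object$var_between + object$var_within)
  out <- list(
    model = object,
    icc = icc,
    variance_ratio = object$var_within / max(object$var_between, 1e-300)
  )
  class(out) <- "summary.usual_intake"
  out
}

#' @export
print.summary.usual_intake <- function(x, ...) {
  print(x$model)
  cat(sprintf(
    "  intraclass correlation = %.3f; within/between variance ratio = %.3f\n",
    x$icc, x$variance_ratio
  ))
  invisible(x)
}

#' @export
coef.usual_intake <- function(object, ...) object$beta

#' @export
residuals.usual_intake <- function(object, ...) {
  if (is.null(object$fit)) {
    return(object$resid)
  }
  # the underlying fit works on a standardized response
  stats::residuals(object$fit, ...) * (object$z_scale %||% 1)
}

gh_rule <- function(n = 9) pracma::gaussHermite(n)

# transformed-scale linear predictor at the day-1 interview level
linpred <- function(object, age_group = NULL, weekend) {
  b <- object$beta
  mu <- unname(b[["(Intercept)"]])
  if ("weekend" %in% names(b)) {
    mu <- mu + unname(b[["weekend"]]) * as.numeric(weekend)
  } else if ("weekendTRUE" %in% names(b)) {
    mu <- mu + unname(b[["weekendTRUE"]]) * as.numeric(weekend)
  }
  if (!is.null(object$age_levels)) {
    if (is.null(age_group)) {
      stop("model includes age_group; supply it in newdata", call. = FALSE)
    }
    term <- paste0("age_group", as.character(age_group))
    extra <- ifelse(term %in% names(b), b[term], 0)
    extra[is.na(extra)] <- 0
    mu <- mu + unname(extra)
  }
  mu
}

# E over within-person error of the inverse Box-Cox, by Gauss-Hermite
# quadrature; mu and b vectorized (recycled to common length)
backtransform_mean <- function(mu, b, object, gh) {
  sigma <- sqrt(object$var_within)
  acc <- 0
  for (k in seq_along(gh$x)) {
    zk <- mu + b + sqrt(2) * sigma * gh$x[k]
    acc <- acc + gh$w[k] * boxcox_inverse(zk, object$lambda)
  }
  val <- acc / sqrt(pi)
  if (any(!is.finite(val))) {
    stop("non-finite value in back-transformation quadrature", call. = FALSE)
  }
  pmax(val - object$offset, 0)
}

#' Usual intake for given covariate profiles and person effects
#'
#' Back-transforms the model to the original intake scale: for each row
#' of `newdata` and person effect `b`, computes the expectation over the
#' within-person error of the inverse Box-Cox of
#' \eqn{x'\beta + b + \epsilon} by 9-point Gauss-Hermite quadrature. The
#' interview-sequence effect is set to its day-1 level, and the weekend
#' covariate is integrated with weights 4/7 weekday and 3/7 weekend
#' (`weekend = "balanced"`) or held at a fixed level.
#'
#' @param object A fitted [fit_usual_intake()] model.
#' @param newdata data.frame of covariate profiles (column `age_group`
#'   when the model used it); defaults to a single baseline profile.
#' @param b Person random effect(s) on the transformed scale, recycled
#'   against the rows of `newdata`.
#' @param weekend `"balanced"`, `"weekday"`, or `"weekend"`.
#' @param gh_points Number of quadrature nodes.
#' @param ... Unused.
#' @return Numeric vector of usual intakes (strictly non-negative).
#' @export
predict.usual_intake <- function(object, newdata = NULL, b = 0,
                                 weekend = c("balanced", "weekday", "weekend"),
                                 gh_points = 9, ...) {
  weekend <- match.arg(weekend)
  gh <- gh_rule(gh_points)
  age <- if (!is.null(newdata) && "age_group" %in% names(newdata)) {
    newdata$age_group
  } else {
    NULL
  }
  n <- max(length(b), if (is.null(age)) 1L else length(age))
  b <- rep_len(b, n)
  if (weekend == "balanced") {
    mu_wd <- linpred(object, age, weekend = FALSE)
    mu_we <- linpred(object, age, weekend = TRUE)
    4 / 7 * backtransform_mean(mu_wd, b, object, gh) +
      3 / 7 * backtransform_mean(mu_we, b, object, gh)
  } else {
    mu <- linpred(object, age, weekend = (weekend == "weekend"))
    backtransform_mean(mu, b, object, gh)
  }
}

#' Usual intake of a single person
#'
#' Convenience wrapper around [predict.usual_intake()] for one covariate
#' profile and one person effect.
#'
#' @param model A fitted `usual_intake` model.
#' @param profile One-row data.frame (or `NULL` for baseline).
#' @param b Person random effect on the transformed scale.
#' @param ... Passed to [predict.usual_intake()].
#' @return Scalar usual intake.
#' @export
usual_intake_of_person <- function(model, profile = NULL, b = 0, ...) {
  predict(model, newdata = profile, b = b, ...)[1L]
}

#' Simulate a population usual-intake distribution
#'
#' The distribution-estimation step: for each person in `persons`, draws
#' `nsim` person effects from \eqn{N(0, \sigma_b^2)}, back-transforms
#' each to a usual intake under the person's covariate profile (weekend
#' balanced 4/7 : 3/7, interview sequence at day 1), and attaches the
#' person's survey weight divided by `nsim`, so the pseudo-population
#' total weight equals the real one. Reproducible given `seed`.
#'
#' @param object A fitted `usual_intake` model.
#' @param nsim Pseudo-persons per real person (default 100).
#' @param seed Integer seed; recorded in the result.
#' @param persons data.frame with `person_id`, `weight`, and `age_group`
#'   when the model used it.
#' @param ... Unused.
#' @return data.frame `person_id`, `replicate`, `usual_intake`, `weight`,
#'   with attributes `seed` and `nutrient`; class `ui_distribution`.
#' @export
simulate.usual_intake <- function(object, nsim = 100, seed = NULL,
                                  persons = NULL, ...) {
  stopifnot(!is.null(persons), all(c("person_id", "weight") %in% names(persons)))
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(persons)
  bmat <- matrix(
    stats::rnorm(np * nsim, 0, sqrt(object$var_between)),
    nrow = np, ncol = nsim
  )
  age <- if (!is.null(object$age_levels)) {
    rep(persons$age_group, times = nsim)
  } else {
    NULL
  }
  nd <- if (is.null(age)) NULL else data.frame(age_group = age)
  ui <- predict(object, newdata = nd, b = as.vector(bmat))
  out <- data.frame(
    person_id = rep(as.character(persons$person_id), times = nsim),
    replicate = rep(seq_len(nsim), each = np),
    usual_intake = ui,
    weight = rep(persons$weight, times = nsim) / nsim,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  attr(out, "nutrient") <- object$nutrient
  class(out) <- c("ui_distribution", "data.frame")
  out
}

#' Population summaries of a usual-intake distribution
#'
#' `mean_ui()` is the survey-weighted mean usual intake. `prev_below_ear()`
#' is the EAR cut-point prevalence of inadequacy: the weighted percent of
#' pseudo-persons whose usual intake is strictly below their age-sex
#' group's Estimated Average Requirement. `prev_at_or_above_ul()` is the
#' weighted percent at or above the Tolerable Upper Intake Level; for a
#' nutrient with no established UL it returns `NA` (never 0).
#'
#' @param dist A `ui_distribution` from [simulate.usual_intake()] (any
#'   data.frame with `person_id`, `usual_intake`, `weight` works).
#' @param weights Optional replacement weights (same length as `dist`
#'   rows), e.g. a BRR replicate.
#' @return `mean_ui()`: a quantity; the prevalences: percents in [0, 100]
#'   or `NA` where the reference value is not established.
#' @export
mean_ui <- function(dist, weights = NULL) {
  w <- if (is.null(weights)) dist$weight else weights
  stats::weighted.mean(dist$usual_intake, w)
}

#' @param dri A [dri_table()].
#' @param demographics data.frame `person_id`, `sex`, `age_years` mapping
#'   each person to an age-sex group.
#' @param nutrient Nutrient identifier (defaults to the distribution's).
#' @rdname mean_ui
#' @export
prev_below_ear <- function(dist, dri, demographics, nutrient = NULL,
                           weights = NULL) {
  ref <- dri_for_persons(dri, demographics, nutrient %||% attr(dist, "nutrient"),
    value = "ear"
  )
  if (all(is.na(ref))) {
    return(NA_real_)
  }
  cutpoint_prevalence(dist, ref, weights, function(x, r) x < r)
}

#' @rdname mean_ui
#' @export
prev_at_or_above_ul <- function(dist, dri, demographics, nutrient = NULL,
                                weights = NULL) {
  ref <- dri_for_persons(dri, demographics, nutrient %||% attr(dist, "nutrient"),
    value = "ul"
  )
  if (all(is.na(ref))) {
    return(NA_real_)
  }
  cutpoint_prevalence(dist, ref, weights, function(x, r) x >= r)
}

cutpoint_prevalence <- function(dist, ref, weights, cmp) {
  r <- ref[match(as.character(dist$person_id), names(ref))]
  if (anyNA(r)) {
    stop("reference value missing for some persons in the distribution",
      call. = FALSE
    )
  }
  w <- if (is.null(weights)) dist$weight else weights
  100 * stats::weighted.mean(cmp(dist$usual_intake, r), w)
}

#' Dietary Reference Intake lookup table
#'
#' EAR and UL per nutrient and age-sex group. An empty/NA `ear` or `ul`
#' means the value is not established for that group.
#'
#' @param df data.frame with columns `nutrient`, `sex` (`"M"`/`"F"`),
#'   `age_min`, `age_max`, `ear`, `ul`.
#' @return A `dri_table`.
#' @export
dri_table <- function(df) {
  req <- c("nutrient", "sex", "age_min", "age_max", "ear", "ul")
  stopifnot(all(req %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  check_nutrient(unique(df$nutrient))
  both <- !is.na(df$ear) & !is.na(df$ul)
  if (any(df$ear[both] >= df$ul[both])) {
    stop("EAR must be below UL where both are present", call. = FALSE)
  }
  structure(df, class = c("dri_table", "data.frame"))
}

#' @rdname dri_table
#' @param path CSV with the `dri_table` columns (empty cells = not
#'   established).
#' @export
read_dri <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$ear <- as.numeric(df$ear)
  df$ul <- as.numeric(df$ul)
  dri_table(df)
}

# named vector of EAR or UL per person; error when a person maps to no
# group, NA when the group exists but the value is not established
dri_for_persons <- function(dri, demographics, nutrient, value = c("ear", "ul")) {
  value <- match.arg(value)
  stopifnot(inherits(dri, "dri_table"))
  if (is.null(nutrient)) stop("nutrient must be given", call. = FALSE)
  sub <- dri[dri$nutrient == nutrient, , drop = FALSE]
  if (!nrow(sub)) {
    stop("no DRI rows for nutrient '", nutrient, "'", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(demographics)), function(i) {
    hit <- sub$sex == demographics$sex[i] &
      sub$age_min <= demographics$age_years[i] &
      demographics$age_years[i] <= sub$age_max
    if (!any(hit)) {
      stop(
        "no DRI group for person ", demographics$person_id[i],
        " (", demographics$sex[i], ", age ", demographics$age_years[i], ")",
        call. = FALSE
      )
    }
    sub[[value]][which(hit)[1L]]
  }, numeric(1))
  stats::setNames(out, as.character(demographics$person_id))
}
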