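#' Apply analytic-sample exclusions to a recall roster
#'
#' Reproduces the standard dietary-survey exclusion cascade: drop persons
#' without the required number of complete recall days, persons below the
#' age threshold, and women who are pregnant or lactating. Exclusions are
#' tallied in that order, so each person is counted under the first rule
#' that removes them.
#'
#' @param persons data.frame with columns `person_id`, `age_years`, `sex`,
#'   `pregnant_or_lactating`, `weight`, `stratum_id`, `psu_id`.
#' @param recalls data.frame with columns `person_id`, `day`,
#'   `complete` (and the food-level columns used downstream).
#' @param age_min Minimum age in years retained (default 19, the adult
#'   cut; age-subgroup runs pass other values).
#' @param require_both_days Require two complete recall days (default);
#'   `FALSE` keeps persons with at least one.
#' @return list with `persons` (retained roster), `recalls` (their recall
#'   lines), and `tally` (data.frame reason/n, including `retained`).
#' @export
apply_exclusions <- function(persons, recalls, age_min = 19,
                             require_both_days = TRUE) {
  stopifnot(
    all(c("person_id", "age_years", "pregnant_or_lactating") %in% names(persons))
  )
  orphan <- setdiff(unique(recalls$person_id), persons$person_id)
  if (length(orphan)) {
    stop(
      "recall lines reference person(s) absent from the roster: ",
      paste(utils::head(orphan, 5), collapse = ", "),
      call. = FALSE
    )
  }
  pd <- unique(recalls[recalls$complete, c("person_id", "day")])
  counts <- table(pd$person_id)
  ndays <- as.integer(counts[match(persons$person_id, names(counts))])
  ndays[is.na(ndays)] <- 0L
  need <- if (require_both_days) 2L else 1L

  reason <- rep(NA_character_, nrow(persons))
  reason[is.na(reason) & ndays < need] <- "incomplete"
  reason[is.na(reason) & persons$age_years < age_min] <- "age"
  reason[is.na(reason) & persons$pregnant_or_lactating] <- "pregnancy/lactation"

  keep <- is.na(reason)
  tally <- as.data.frame(table(reason = reason[!keep]), stringsAsFactors = FALSE)
  names(tally) <- c("reason", "n")
  tally <- rbind(tally, data.frame(reason = "retained", n = sum(keep)))
  retained <- persons[keep, , drop = FALSE]
  list(
    persons = retained,
    recalls = recalls[recalls$person_id %in% retained$person_id, , drop = FALSE],
    tally = tally
  )
}

#' Merge recall lines with a food database into person-day intakes
#'
#' For every recall line, the amount of each nutrient is
#' `grams_consumed * total_per_100g / 100`, split into intrinsic,
#' enriched and fortified components by the database's source
#' percentages, then summed per (person, day, nutrient).
#'
#' @param recalls data.frame with `person_id`, `day`, `food_id`,
#'   `grams_consumed` (plus `weekend`, carried through when present).
#' @param fd A [food_db()].
#' @param unknown_foods `"error"` (default) fails on a food code absent
#'   from the database; `"drop"` skips such lines and reports coverage.
#' @return data.frame of person-day intakes: `person_id`, `day`,
#'   `nutrient`, `amount_total`, `amount_intrinsic`, `amount_enriched`,
#'   `amount_fortified` (plus `weekend`). Attribute `coverage` gives the
#'   fraction of recall grams matched when `unknown_foods = "drop"`.
#' @export
merge_recalls <- function(recalls, fd, unknown_foods = c("error", "drop")) {
  stopifnot(inherits(fd, "food_db"))
  unknown_foods <- match.arg(unknown_foods)
  recalls <- as.data.frame(recalls)
  known <- recalls$food_id %in% fd$food_id
  coverage <- 1
  if (!all(known)) {
    if (unknown_foods == "error") {
      stop(
        "unknown food code(s) in recalls: ",
        paste(utils::head(unique(recalls$food_id[!known]), 5), collapse = ", "),
        call. = FALSE
      )
    }
    tot <- sum(recalls$grams_consumed)
    coverage <- if (tot > 0) sum(recalls$grams_consumed[known]) / tot else 1
    recalls <- recalls[known, , drop = FALSE]
  }

  fdd <- as.data.frame(fd)
  m <- merge(recalls, fdd,
    by = "food_id", all.x = TRUE, sort = FALSE,
    suffixes = c("", ".fd")
  )
  amt <- m$grams_consumed * m$total_per_100g / 100
  key <- interaction(m$person_id, m$day, m$nutrient, drop = TRUE)
  agg <- function(x) as.numeric(tapply(x, key, sum))
  first <- function(x) {
    as.vector(tapply(x, key, `[`, 1L))
  }
  out <- data.frame(
    person_id = first(as.character(m$person_id)),
    day = as.integer(first(m$day)),
    nutrient = first(as.character(m$nutrient)),
    amount_total = agg(amt),
    amount_intrinsic = agg(amt * m$pct_intrinsic / 100),
    amount_enriched = agg(amt * m$pct_enriched / 100),
    amount_fortified = agg(amt * m$pct_fortified / 100),
    stringsAsFactors = FALSE
  )
  if ("weekend" %in% names(m)) out$weekend <- as.logical(first(m$weekend))
  out <- out[order(out$person_id, out$day, out$nutrient), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  out
}

#' Fortified intake as a percent of the Daily Value
#'
#' A person's mean daily intake of a nutrient from voluntarily fortified
#' foods, averaged over their available recall days, expressed as a
#' percent of the Daily Value. This is the quantity on which the
#' fortification-exposure subgroups are defined.
#'
#' @param intakes Person-day intakes from [merge_recalls()] (one person or
#'   many; shares are computed per person).
#' @param nutrient Nutrient identifier.
#' @param dv A [dv_table()].
#' @return Named numeric vector of percents, one per person present.
#' @export
fortified_share_of_dv <- function(intakes, nutrient, dv) {
  dvn <- dv_lookup(dv, nutrient)
  sub <- intakes[intakes$nutrient == nutrient, , drop = FALSE]
  if (!nrow(sub)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  daily <- tapply(sub$amount_fortified, sub$person_id, mean)
  stats::setNames(100 * as.numeric(daily) / dvn, names(daily))
}

#' Assign fortification-exposure subgroups
#'
#' Partitions persons by how much of the Daily Value they obtain from
#' fortified foods: none (`zero`), more than zero up to half
#' (`gt0_le50`), or more than half (`gt50`).
#'
#' @param share Percent of DV from fortified foods (vectorized, >= 0).
#' @return Factor with levels `zero`, `gt0_le50`, `gt50`.
#' @export
#' @examples
#' assign_subgroup(c(0, 50, 50.01))
assign_subgroup <- function(share) {
  stopifnot(is.numeric(share))
  if (any(share < 0, na.rm = TRUE)) {
    stop("fortified share must be non-negative", call. = FALSE)
  }
  lev <- ifelse(share == 0, "zero", ifelse(share <= 50, "gt0_le50", "gt50"))
  factor(lev, levels = c("zero", "gt0_le50", "gt50"))
}
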