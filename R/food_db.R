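#' Construct a source-partitioned food composition database
#'
#' Each row describes one food x nutrient pair: the total amount of the
#' nutrient per 100 g edible portion, the percentage split of that total
#' across the three sources recognized on US labels — intrinsic
#' (naturally occurring), enriched (mandatory restoration), fortified
#' (voluntary addition) — plus the FDA Reference Amount Customarily
#' Consumed (RACC) in grams, on which claims are evaluated.
#'
#' @param entries data.frame with columns `food_id`, `nutrient`,
#'   `total_per_100g`, `pct_intrinsic`, `pct_enriched`, `pct_fortified`,
#'   `racc_g`, and optionally `food_desc`.
#' @param label Character tag (e.g. `"Original"`, `"Modified"`).
#' @return Object of class `food_db` (a validated data.frame).
#' @export
food_db <- function(entries, label = "Original") {
  req <- c(
    "food_id", "nutrient", "total_per_100g", "pct_intrinsic",
    "pct_enriched", "pct_fortified", "racc_g"
  )
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop("food_db is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  check_nutrient(unique(entries$nutrient))
  if (anyDuplicated(entries[c("food_id", "nutrient")])) {
    stop("duplicate (food_id, nutrient) entries", call. = FALSE)
  }
  validate_food_db_entries(entries)
  structure(entries, label = label, class = c("food_db", "data.frame"))
}

validate_food_db_entries <- function(e, tol = 1e-6) {
  num <- c(
    "total_per_100g", "pct_intrinsic", "pct_enriched", "pct_fortified",
    "racc_g"
  )
  for (cl in num) {
    if (!is.numeric(e[[cl]]) || anyNA(e[[cl]])) {
      stop("column ", cl, " must be numeric without NA", call. = FALSE)
    }
  }
  if (any(e$total_per_100g < 0)) stop("negative total_per_100g", call. = FALSE)
  if (any(e$racc_g <= 0)) stop("racc_g must be positive", call. = FALSE)
  pct <- e$pct_intrinsic + e$pct_enriched + e$pct_fortified
  pos <- e$total_per_100g > 0
  if (any(abs(pct[pos] - 100) > tol)) {
    stop("source percentages must sum to 100 where total > 0", call. = FALSE)
  }
  if (any(abs(pct[!pos]) > tol)) {
    stop("source percentages must be 0 where total is 0", call. = FALSE)
  }
  cols <- c("pct_intrinsic", "pct_enriched", "pct_fortified")
  if (any(unlist(e[cols]) < -tol) || any(unlist(e[cols]) > 100 + tol)) {
    stop("source percentages must lie in [0, 100]", call. = FALSE)
  }
  invisible(e)
}

#' @export
print.food_db <- function(x, ...) {
  cat(
    "Food database '", attr(x, "label"), "': ",
    length(unique(x$food_id)), " foods, ",
    length(unique(x$nutrient)), " nutrients, ",
    nrow(x), " entries\n",
    sep = ""
  )
  invisible(x)
}

# amounts of each source component in canonical units per 100 g
source_amounts <- function(fd) {
  data.frame(
    food_id = fd$food_id,
    nutrient = fd$nutrient,
    intrinsic = fd$total_per_100g * fd$pct_intrinsic / 100,
    enriched = fd$total_per_100g * fd$pct_enriched / 100,
    fortified = fd$total_per_100g * fd$pct_fortified / 100,
    stringsAsFactors = FALSE
  )
}

#' Read / write a food database as CSV
#'
#' Columns: `food_id, food_desc, nutrient, total_per_100g, pct_intrinsic,
#' pct_enriched, pct_fortified, racc_g` (UTF-8, header, '.' decimal).
#'
#' @param path CSV path.
#' @param fd A `food_db` (for writing).
#' @param label Label for the database read in.
#' @return `read_food_db()` returns a `food_db`.
#' @export
read_food_db <- function(path, label = "Original") {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  food_db(e, label = label)
}

#' @rdname read_food_db
#' @export
write_food_db <- function(fd, path) {
  stopifnot(inherits(fd, "food_db"))
  utils::write.csv(as.data.frame(fd), path, row.names = FALSE)
  invisible(path)
}

#' Rewrite voluntary fortification for an updated Daily Value table
#'
#' Constructs the counterfactual ("Modified") database in which every
#' voluntarily fortified food keeps the same percent-DV under the new DVs
#' that it had under the old ones. Per (food, nutrient) with intrinsic,
#' enriched and fortified amounts I, E, F and total T = I + E + F:
#'
#' \deqn{F' = \max(0,\; T \cdot DV_{new}/DV_{old} - I - E)}
#'
#' Intrinsic and enriched amounts are never altered (intrinsic content is
#' a property of the food; enrichment levels are fixed by regulation).
#' When I + E alone meet or exceed the target total, fortification is
#' dropped entirely and the food becomes non-fortified — the only
#' fortification-status change the rewrite can make; a non-fortified food
#' is never made fortified. Nutrients in `frozen_nutrients` (by default
#' vitamin E and folate, whose added chemical forms cannot be resolved
#' from label data) are copied unchanged.
#'
#' @param original A `food_db`.
#' @param current,updated [dv_table()] objects (canonical units).
#' @param frozen_nutrients Nutrients exempt from rewriting.
#' @param tol Relative tolerance below which a residual fortified amount
#'   is treated as exactly zero (guards against floating-point dust
#'   reclassifying a food as fortified).
#' @return A `food_db` labeled `"Modified"`.
#' @export
#' @examples
#' fd <- food_db(data.frame(
#'   food_id = "f1", nutrient = "vit_b12", total_per_100g = 6,
#'   pct_intrinsic = 0, pct_enriched = 0, pct_fortified = 100, racc_g = 100
#' ))
#' build_modified_fd(fd, dv_current(), dv_updated())$total_per_100g # 2.4
build_modified_fd <- function(original, current, updated,
                              frozen_nutrients = c("vit_e", "folate_dfe"),
                              tol = 1e-12) {
  stopifnot(inherits(original, "food_db"))
  out <- as.data.frame(original)
  nutr <- unique(out$nutrient)
  for (n in setdiff(nutr, frozen_nutrients)) {
    # fail fast if a DV is missing for any rewritten nutrient
    dv_lookup(current, n)
    dv_lookup(updated, n)
  }
  src <- source_amounts(original)
  ratio <- vapply(out$nutrient, function(n) {
    if (n %in% frozen_nutrients) NA_real_ else {
      dv_lookup(updated, n) / dv_lookup(current, n)
    }
  }, numeric(1))
  # a DV ratio of exactly 1 is an algebraic identity on every entry;
  # skipping it keeps unchanged nutrients bit-identical
  rewrite <- !(out$nutrient %in% frozen_nutrients) & src$fortified > 0 &
    !is.na(ratio) & ratio != 1
  i <- which(rewrite)
  if (length(i)) {
    target <- out$total_per_100g[i] * ratio[i]
    f_new <- pmax(0, target - src$intrinsic[i] - src$enriched[i])
    t_new <- src$intrinsic[i] + src$enriched[i] + f_new
    if (any(f_new < 0) || any(t_new < 0)) {
      stop("internal consistency error: negative rewritten amount",
        call. = FALSE
      )
    }
    f_new[f_new < tol * pmax(t_new, .Machine$double.xmin)] <- 0
    t_new <- src$intrinsic[i] + src$enriched[i] + f_new
    out$total_per_100g[i] <- t_new
    zero <- t_new == 0
    out$pct_intrinsic[i] <- ifelse(zero, 0, 100 * src$intrinsic[i] / t_new)
    out$pct_enriched[i] <- ifelse(zero, 0, 100 * src$enriched[i] / t_new)
    out$pct_fortified[i] <- ifelse(zero, 0, 100 * f_new / t_new)
  }
  food_db(out, label = "Modified")
}

#' Count fortified and enriched foods per nutrient
#'
#' A food counts as fortified for a nutrient if any of its amount is
#' voluntarily added, enriched if any comes from mandatory enrichment; a
#' food fortified and enriched counts in both columns.
#'
#' @param fd A `food_db`.
#' @return data.frame with columns `nutrient`, `n_fortified`, `n_enriched`.
#' @export
count_fortified_enriched <- function(fd) {
  stopifnot(inherits(fd, "food_db"))
  nutr <- all_nutrients()
  present <- nutr[nutr %in% fd$nutrient]
  res <- data.frame(
    nutrient = nutr,
    n_fortified = 0L,
    n_enriched = 0L,
    stringsAsFactors = FALSE
  )
  for (n in present) {
    sub <- fd[fd$nutrient == n, ]
    res$n_fortified[res$nutrient == n] <-
      sum(sub$pct_fortified > 0 & sub$total_per_100g > 0)
    res$n_enriched[res$nutrient == n] <-
      sum(sub$pct_enriched > 0 & sub$total_per_100g > 0)
  }
  res
}

#' Count good / excellent source claims per nutrient
#'
#' Evaluates each food's nutrient amount per RACC
#' (`total_per_100g * racc_g / 100`) against a DV table and counts foods
#' whose unrounded percent-DV reaches the good-source (10-19%) or
#' excellent-source (>= 20%) claim thresholds.
#'
#' @param fd A `food_db`.
#' @param dv A [dv_table()].
#' @param fda_rounding Passed to [classify_claim()].
#' @return data.frame with columns `nutrient`, `n_good`, `n_excellent`.
#' @export
count_claims <- function(fd, dv, fda_rounding = FALSE) {
  stopifnot(inherits(fd, "food_db"))
  nutr <- all_nutrients()
  res <- data.frame(
    nutrient = nutr,
    n_good = 0L,
    n_excellent = 0L,
    stringsAsFactors = FALSE
  )
  for (n in intersect(nutr, unique(fd$nutrient))) {
    sub <- fd[fd$nutrient == n, ]
    per_racc <- sub$total_per_100g * sub$racc_g / 100
    cl <- classify_claim(percent_dv(per_racc, n, dv), fda_rounding)
    res$n_good[res$nutrient == n] <- sum(cl == "good")
    res$n_excellent[res$nutrient == n] <- sum(cl == "excellent")
  }
  res
}
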