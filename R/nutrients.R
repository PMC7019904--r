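#' Modeled nutrients and their canonical units
#'
#' The thirteen label nutrients handled by the package, each with the
#' canonical unit in which every amount and Daily Value is stored
#' internally: activity-adjusted units where the field uses them
#' (µg RAE for vitamin A, mg NE for niacin, µg DFE for folate) and
#' plain mass units otherwise. All arithmetic in the package happens in
#' canonical units; label units such as IU are converted at load time
#' with [convert_amount()].
#'
#' @return A data.frame with columns `nutrient` (identifier),
#'   `canonical_unit`, and `display` (human-readable name).
#' @export
#' @examples
#' nutrient_registry()
nutrient_registry <- function() {
  data.frame(
    nutrient = c(
      "vit_a", "thiamin", "riboflavin", "niacin", "vit_b6", "vit_b12",
      "vit_c", "vit_d", "vit_e", "folate_dfe", "calcium", "iron", "zinc"
    ),
    canonical_unit = c(
      "ug_rae", "mg", "mg", "mg_ne", "mg", "ug",
      "mg", "ug", "mg", "ug_dfe", "mg", "mg", "mg"
    ),
    display = c(
      "Vitamin A", "Thiamin", "Riboflavin", "Niacin", "Vitamin B6",
      "Vitamin B12", "Vitamin C", "Vitamin D", "Vitamin E",
      "Folate (DFE)", "Calcium", "Iron", "Zinc"
    ),
    stringsAsFactors = FALSE
  )
}

all_nutrients <- function() nutrient_registry()$nutrient

canonical_unit <- function(nutrient) {
  reg <- nutrient_registry()
  check_nutrient(nutrient)
  reg$canonical_unit[match(nutrient, reg$nutrient)]
}

check_nutrient <- function(nutrient) {
  bad <- setdiff(nutrient, all_nutrients())
  if (length(bad)) {
    stop("unknown nutrient(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(nutrient)
}

# unicode micro signs and unit spellings normalized to ascii identifiers
normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", unit)
  u <- gsub("[ -]", "_", tolower(trimws(u)))
  aliases <- c(
    "iu" = "IU", "ug" = "ug", "mcg" = "ug", "mg" = "mg",
    "ug_rae" = "ug_rae", "rae" = "ug_rae",
    "mg_ne" = "mg_ne", "ne" = "mg_ne",
    "ug_dfe" = "ug_dfe", "dfe" = "ug_dfe",
    "mg_tryptophan" = "mg_tryptophan", "mg_trp" = "mg_tryptophan",
    "ug_folic_acid" = "ug_folic_acid", "ug_fa" = "ug_folic_acid"
  )
  out <- unname(aliases[u])
  if (anyNA(out)) {
    stop("unrecognized unit(s): ", paste(unit[is.na(out)], collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Supported label-unit conversions, one row per (nutrient, from, to).
# Factors follow the label conventions: 40 IU vitamin D per ug;
# 1 IU vitamin A (as retinol) = 0.3 ug RAE; 30 IU vitamin E = 15 mg;
# 60 mg tryptophan = 1 mg NE; 0.6 ug folic acid = 1 ug DFE.
conversion_table <- function() {
  rbind(
    data.frame(nutrient = "vit_d", from = "IU", to = "ug", factor = 1 / 40),
    data.frame(nutrient = "vit_d", from = "ug", to = "IU", factor = 40),
    data.frame(nutrient = "vit_a", from = "IU", to = "ug_rae", factor = 0.3),
    data.frame(nutrient = "vit_a", from = "ug_rae", to = "IU", factor = 1 / 0.3),
    data.frame(nutrient = "vit_e", from = "IU", to = "mg", factor = 0.5),
    data.frame(nutrient = "vit_e", from = "mg", to = "IU", factor = 2),
    data.frame(nutrient = "niacin", from = "mg", to = "mg_ne", factor = 1),
    data.frame(nutrient = "niacin", from = "mg_ne", to = "mg", factor = 1),
    data.frame(nutrient = "niacin", from = "mg_tryptophan", to = "mg_ne", factor = 1 / 60),
    data.frame(nutrient = "folate_dfe", from = "ug_folic_acid", to = "ug_dfe", factor = 1 / 0.6),
    data.frame(nutrient = "folate_dfe", from = "ug", to = "ug_dfe", factor = 1)
  )
}

#' Convert a nutrient amount between label units
#'
#' Converts between a nutrient's canonical unit and the label units the
#' field still prints (IU for vitamins A, D and E; mg tryptophan for
#' niacin equivalents; µg folic acid for dietary folate equivalents).
#' Only explicitly supported pairs are converted; anything else is an
#' error rather than a silent pass-through, so a unit mix-up in an input
#' file fails loudly.
#'
#' @param value Numeric amount (vectorized).
#' @param nutrient A single nutrient identifier from [nutrient_registry()].
#' @param from,to Unit strings (e.g. `"IU"`, `"ug"`, `"ug_rae"`; `"µg"` is
#'   accepted as a spelling of `"ug"`).
#' @return `value` expressed in `to`.
#' @export
#' @examples
#' convert_amount(400, "vit_d", "IU", "ug") # 10
#' convert_amount(5000, "vit_a", "IU", "ug_rae") # 1500
convert_amount <- function(value, nutrient, from, to) {
  stopifnot(is.numeric(value), length(nutrient) == 1L)
  check_nutrient(nutrient)
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  if (from == to) {
    return(value)
  }
  tab <- conversion_table()
  hit <- tab$nutrient == nutrient & tab$from == from & tab$to == to
  if (!any(hit)) {
    stop(
      "unsupported unit conversion for ", nutrient, ": ", from, " -> ", to,
      call. = FALSE
    )
  }
  value * tab$factor[which(hit)[1L]]
}

#' Construct a Daily Value table
#'
#' A DV table maps each modeled nutrient to its labeled Daily Value. Two
#' instances — the pre-2020 table ([dv_current()]) and the updated table
#' ([dv_updated()]) — drive a rewrite scenario; arbitrary tables can be
#' built for synthetic scenarios. Values are stored in each nutrient's
#' canonical unit; pass `unit` entries to convert label units on input.
#'
#' @param values Named numeric vector, names are nutrient identifiers.
#' @param scenario_label Character tag carried through reports.
#' @param units Optional named character vector of the units `values` are
#'   expressed in; defaults to canonical units.
#' @return An object of class `dv_table`: a named numeric vector (canonical
#'   units) with a `scenario_label` attribute.
#' @export
#' @examples
#' dv_table(c(vit_d = 400, calcium = 1000), "toy", units = c(vit_d = "IU"))
dv_table <- function(values, scenario_label = "custom", units = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  check_nutrient(names(values))
  if (any(values <= 0 | !is.finite(values))) {
    stop("Daily Values must be positive and finite", call. = FALSE)
  }
  out <- values
  if (!is.null(units)) {
    for (nm in names(units)) {
      out[nm] <- convert_amount(out[nm], nm, units[[nm]], canonical_unit(nm))
    }
  }
  structure(out, scenario_label = scenario_label, class = "dv_table")
}

#' @export
print.dv_table <- function(x, ...) {
  cat("Daily Value table:", attr(x, "scenario_label"), "\n")
  reg <- nutrient_registry()
  df <- data.frame(
    nutrient = names(x),
    dv = as.numeric(x),
    unit = reg$canonical_unit[match(names(x), reg$nutrient)]
  )
  print(df, row.names = FALSE)
  invisible(x)
}

dv_lookup <- function(dv, nutrient) {
  stopifnot(inherits(dv, "dv_table"))
  if (!nutrient %in% names(dv)) {
    stop(
      "no Daily Value for nutrient '", nutrient, "' in table '",
      attr(dv, "scenario_label"), "'",
      call. = FALSE
    )
  }
  unname(dv[[nutrient]])
}

#' Built-in Daily Value tables
#'
#' The pre-2020 ("Current") and post-2020 ("Updated") FDA Daily Values for
#' the thirteen modeled nutrients, already normalized to canonical units
#' (vitamin A 5000 IU retinol = 1500 µg RAE; vitamin D 400 IU = 10 µg;
#' vitamin E 30 IU = 15 mg).
#'
#' @return A `dv_table`.
#' @export
#' @examples
#' dv_current()
dv_current <- function() {
  dv_table(
    c(
      vit_a = 1500, thiamin = 1.5, riboflavin = 1.7, niacin = 20,
      vit_b6 = 2.0, vit_b12 = 6.0, vit_c = 60, vit_d = 10, vit_e = 15,
      folate_dfe = 400, calcium = 1000, iron = 18, zinc = 15
    ),
    scenario_label = "Current DV"
  )
}

#' @rdname dv_current
#' @export
dv_updated <- function() {
  dv_table(
    c(
      vit_a = 900, thiamin = 1.2, riboflavin = 1.3, niacin = 16,
      vit_b6 = 1.7, vit_b12 = 2.4, vit_c = 90, vit_d = 20, vit_e = 15,
      folate_dfe = 400, calcium = 1300, iron = 18, zinc = 11
    ),
    scenario_label = "Updated DV"
  )
}

#' Percent of the Daily Value supplied by an amount
#'
#' @param amount Nutrient amount in canonical units (vectorized).
#' @param nutrient Single nutrient identifier.
#' @param dv A [dv_table()].
#' @return `100 * amount / DV`, unrounded.
#' @export
#' @examples
#' percent_dv(2.4, "vit_d", dv_updated()) # 12.5
percent_dv <- function(amount, nutrient, dv) {
  stopifnot(is.numeric(amount))
  if (any(amount < 0, na.rm = TRUE)) {
    stop("amount must be non-negative", call. = FALSE)
  }
  100 * amount / dv_lookup(dv, nutrient)
}

#' Classify a nutrient content claim from a percent-DV
#'
#' US label regulations allow an "excellent source" (or "high") claim at
#' >= 20% DV per RACC and a "good source" claim at 10-19% DV per RACC.
#' Classification uses the unrounded percent by default; `fda_rounding`
#' first rounds to the nearest whole percent, as label panels do.
#'
#' @param pdv Percent of DV per RACC (vectorized, non-negative).
#' @param fda_rounding Round to the nearest integer percent before
#'   classifying.
#' @return Factor with levels `none < good < excellent`.
#' @export
#' @examples
#' classify_claim(c(25, 12.5, 9.99))
classify_claim <- function(pdv, fda_rounding = FALSE) {
  stopifnot(is.numeric(pdv))
  if (any(pdv < 0, na.rm = TRUE)) {
    stop("percent DV must be non-negative", call. = FALSE)
  }
  if (fda_rounding) pdv <- round(pdv)
  lev <- ifelse(pdv >= 20, "excellent", ifelse(pdv >= 10, "good", "none"))
  factor(lev, levels = c("none", "good", "excellent"), ordered = TRUE)
}

#' Signed percent change between two Daily Value tables
#'
#' The relative change of the Daily Value for one nutrient, rounded to
#' the nearest integer percent (the resolution at which DV revisions are
#' reported); decreases are negative.
#'
#' @param nutrient Nutrient identifier.
#' @param current,updated [dv_table()] objects in canonical units.
#' @return Integer-valued percent change.
#' @export
#' @examples
#' dv_percent_change("vit_b12", dv_current(), dv_updated()) # -60
dv_percent_change <- function(nutrient, current, updated) {
  old <- dv_lookup(current, nutrient)
  new <- dv_lookup(updated, nutrient)
  round(100 * (new - old) / old)
}

#' Read / write a Daily Value table as JSON
#'
#' The interchange format is
#' `{"scenario_label": ..., "values": {"<nutrient>": {"amount": x, "unit": u}}}`.
#'
#' @param path File path.
#' @param dv A `dv_table` (for writing).
#' @return `read_dv_json()` returns a `dv_table`.
#' @export
read_dv_json <- function(path) {
  obj <- jsonlite::read_json(path)
  vals <- vapply(obj$values, function(v) as.numeric(v$amount), numeric(1))
  units <- vapply(obj$values, function(v) as.character(v$unit), character(1))
  dv_table(vals,
    scenario_label = obj$scenario_label %||% "unnamed",
    units = units
  )
}

#' @rdname read_dv_json
#' @export
write_dv_json <- function(dv, path) {
  stopifnot(inherits(dv, "dv_table"))
  reg <- nutrient_registry()
  vals <- lapply(seq_along(dv), function(i) {
    nm <- names(dv)[i]
    list(amount = unname(dv[[i]]), unit = reg$canonical_unit[reg$nutrient == nm])
  })
  names(vals) <- names(dv)
  jsonlite::write_json(
    list(scenario_label = attr(dv, "scenario_label"), values = vals),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
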