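#' Run a paired Daily-Value scenario comparison
#'
#' Reproduces the study design of a DV-update impact analysis end to
#' end on synthetic (or supplied) data: build the rewritten ("Modified")
#' food database with [build_modified_fd()], merge the *same* two-day
#' recalls against the original database under the current DV table and
#' against the modified database under the updated table, and for each
#' nutrient estimate fortification-exposure subgroup sizes, food counts,
#' claim counts, mean usual intake, percent below the EAR and percent at
#' or above the UL, with BRR standard errors. Both arms share the
#' population, weights, design and random seeds, so every difference
#' between the two reports is attributable to the DV change alone.
#'
#' @param config A [generator_config()]; its seed drives all randomness.
#' @param dv_cur,dv_upd The two [dv_table()]s defining the scenario.
#' @param data Optional pre-generated data list
#'   (`persons`/`recalls`/`design`, as returned by
#'   [generate_population_and_recalls()]); generated from `config` when
#'   `NULL`.
#' @param fd Optional original [food_db()]; generated when `NULL`.
#' @param dri Optional [dri_table()]; a synthetic one anchored at the
#'   40th / 97.5th true-usual-intake percentiles is built when `NULL`
#'   and generator truth is available.
#' @param n_mc Pseudo-persons per person in the distribution step.
#' @param fay Fay coefficient for the BRR weights.
#' @param age_min Minimum age retained in the analytic sample.
#' @param frozen_nutrients Passed to [build_modified_fd()].
#' @param brr_full Refit the usual-intake model under each replicate
#'   weight set (slow) instead of replicating only the final weighted
#'   statistics (default).
#' @return Object of class `scenario_pair`: list with elements `current`
#'   and `updated` (each a scenario report: `label`, `counts`, `claims`,
#'   `estimates`, `subgroup_sizes`), plus `exclusions`, `dri`, and
#'   `provenance`.
#' @export
run_scenario_pair <- function(config = generator_config(),
                              dv_cur = dv_current(),
                              dv_upd = dv_updated(),
                              data = NULL, fd = NULL, dri = NULL,
                              n_mc = 100, fay = 0.3, age_min = 19,
                              frozen_nutrients = c("vit_e", "folate_dfe"),
                              brr_full = FALSE) {
  if (is.null(fd)) fd <- generate_food_db(config)
  if (is.null(data)) data <- generate_population_and_recalls(config, fd)
  fd_mod <- build_modified_fd(fd, dv_cur, dv_upd,
    frozen_nutrients = frozen_nutrients
  )

  excl <- apply_exclusions(data$persons, data$recalls, age_min = age_min)
  persons <- excl$persons
  recalls <- excl$recalls[excl$recalls$complete, , drop = FALSE]

  if (is.null(dri) && !is.null(data$truth)) {
    truth_kept <- data$truth[data$truth$person_id %in% persons$person_id, ]
    dri <- synthetic_dri(truth_kept, persons,
      no_ul = intersect(config$no_ul, config$nutrients)
    )
  }

  reps <- build_replicates(
    persons[c("person_id", "stratum_id", "psu_id")],
    persons$weight,
    fay = fay
  )
  nutrients <- intersect(config$nutrients, unique(fd$nutrient))
  seed_base <- config$seed + 5000L

  current <- scenario_report(
    "Current DV", fd, dv_cur, persons, recalls, reps, dri,
    nutrients, n_mc, seed_base, brr_full
  )
  updated <- scenario_report(
    "Updated DV", fd_mod, dv_upd, persons, recalls, reps, dri,
    nutrients, n_mc, seed_base, brr_full
  )

  structure(
    list(
      current = current,
      updated = updated,
      exclusions = excl$tally,
      dri = dri,
      provenance = list(
        seed = config$seed, n_mc = n_mc, fay = fay,
        age_min = age_min, nutrients = nutrients,
        n_persons_analytic = nrow(persons),
        package = as.character(utils::packageVersion("fortiscope"))
      )
    ),
    class = "scenario_pair"
  )
}

# one arm: counts, claims, per-nutrient subgroup sizes and estimates
scenario_report <- function(label, fd, dv, persons, recalls, reps, dri,
                            nutrients, n_mc, seed_base, brr_full = FALSE) {
  intakes <- merge_recalls(recalls, fd)
  est_rows <- list()
  size_rows <- list()
  for (j in seq_along(nutrients)) {
    n <- nutrients[j]
    nd <- intakes[intakes$nutrient == n, , drop = FALSE]
    if (!nrow(nd)) next
    nd$age_group <- persons$age_group[match(nd$person_id, persons$person_id)]

    share <- fortified_share_of_dv(nd, n, dv)
    subgroup <- assign_subgroup(share)
    pers_n <- persons[match(names(share), persons$person_id), , drop = FALSE]

    model <- fit_usual_intake(nd, nutrient = n)
    dist <- simulate(model,
      nsim = n_mc, seed = seed_base + j, persons = pers_n
    )

    sizes <- table(subgroup)
    size_rows[[j]] <- data.frame(
      nutrient = n,
      n_analytic = length(share),
      n_zero = as.integer(sizes[["zero"]]),
      n_gt0_le50 = as.integer(sizes[["gt0_le50"]]),
      n_gt50 = as.integer(sizes[["gt50"]]),
      stringsAsFactors = FALSE
    )

    groups <- list(
      overall = rep(TRUE, length(share)),
      zero = subgroup == "zero",
      gt0_le50 = subgroup == "gt0_le50",
      gt50 = subgroup == "gt50"
    )
    for (g in names(groups)) {
      keep_ids <- names(share)[groups[[g]]]
      est_rows[[length(est_rows) + 1L]] <- estimate_block(
        n, g, dist, keep_ids, reps, dri, persons, n_mc,
        model_data = if (brr_full) nd else NULL, n_mc_full = n_mc,
        seed_sim = seed_base + j
      )
    }
  }
  list(
    label = label,
    counts = count_fortified_enriched(fd),
    claims = count_claims(fd, dv),
    subgroup_sizes = do.call(rbind, size_rows),
    estimates = do.call(rbind, est_rows)
  )
}

# weighted mean / cut-point stats for one nutrient x subgroup, BRR SEs
estimate_block <- function(nutrient, group, dist, keep_ids, reps, dri,
                           persons, n_mc, model_data = NULL, n_mc_full = 100,
                           seed_sim = NULL) {
  sub <- dist[dist$person_id %in% keep_ids, , drop = FALSE]
  empty <- nrow(sub) == 0L
  demo <- persons[persons$person_id %in% keep_ids,
    c("person_id", "sex", "age_years"),
    drop = FALSE
  ]
  design_ids <- as.character(reps$design$person_id)

  make_stat <- function(fn) {
    if (is.null(model_data)) {
      # default: replicate only the final weighted statistic over the
      # already-simulated usual-intake distribution
      function(data, weights) {
        w <- weights[match(as.character(data$person_id), design_ids)] / n_mc
        fn(data, w)
      }
    } else {
      # full-pipeline replication: refit (precision-weighted) and
      # re-simulate under each replicate weight set
      function(data, weights) {
        md <- model_data
        md$.w <- weights[match(as.character(md$person_id), design_ids)]
        m <- refit_weighted(md, nutrient)
        pers <- persons[match(unique(as.character(md$person_id)),
          persons$person_id
        ), , drop = FALSE]
        pers$weight <- weights[match(pers$person_id, design_ids)]
        d2 <- simulate(m, nsim = n_mc_full, seed = seed_sim, persons = pers)
        d2 <- d2[d2$person_id %in% keep_ids, , drop = FALSE]
        fn(d2, d2$weight)
      }
    }
  }

  stat_defs <- list(
    mean_ui = function(d, w) mean_ui(d, weights = w),
    pct_below_ear = function(d, w) {
      if (is.null(dri)) NA_real_ else prev_below_ear(d, dri, demo, nutrient, w)
    },
    pct_at_or_above_ul = function(d, w) {
      if (is.null(dri)) {
        NA_real_
      } else {
        prev_at_or_above_ul(d, dri, demo, nutrient, w)
      }
    }
  )
  rows <- lapply(names(stat_defs), function(s) {
    if (empty) {
      return(data.frame(
        nutrient = nutrient, subgroup = group, stat = s,
        estimate = NA_real_, se = NA_real_, n = 0L,
        stringsAsFactors = FALSE
      ))
    }
    res <- brr_se(make_stat(stat_defs[[s]]), sub, reps)
    data.frame(
      nutrient = nutrient, subgroup = group, stat = s,
      estimate = res$estimate, se = res$se, n = length(keep_ids),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

refit_weighted <- function(md, nutrient) {
  # replicate weights enter the mixed fit as prior weights
  fit_usual_intake(md, nutrient = nutrient, sample_weights = md$.w)
}

#' @export
print.scenario_pair <- function(x, ...) {
  cat("Daily-Value scenario comparison\n")
  cat(
    "  analytic sample:", x$provenance$n_persons_analytic, "persons;",
    length(x$provenance$nutrients), "nutrients; seed",
    x$provenance$seed, "\n\n"
  )
  tab <- scenario_table(x)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Side-by-side rendering of a scenario pair
#'
#' Wide table with one row per nutrient: overall mean usual intake,
#' percent below EAR and percent at or above UL under each arm.
#'
#' @param pair A [run_scenario_pair()] result.
#' @return data.frame.
#' @export
scenario_table <- function(pair) {
  pick <- function(rep, stat) {
    e <- rep$estimates
    e <- e[e$subgroup == "overall" & e$stat == stat, ]
    stats::setNames(e$estimate, e$nutrient)
  }
  nutr <- unique(pair$current$estimates$nutrient)
  data.frame(
    nutrient = nutr,
    ui_current = pick(pair$current, "mean_ui")[nutr],
    ui_updated = pick(pair$updated, "mean_ui")[nutr],
    pct_below_ear_current = pick(pair$current, "pct_below_ear")[nutr],
    pct_below_ear_updated = pick(pair$updated, "pct_below_ear")[nutr],
    pct_ul_current = pick(pair$current, "pct_at_or_above_ul")[nutr],
    pct_ul_updated = pick(pair$updated, "pct_at_or_above_ul")[nutr],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
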