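test_that("food_db enforces its invariants", {
  expect_error(
    food_db(fd_entry(pi = 50, pe = 0, pf = 40)),
    "sum to 100"
  )
  expect_error(
    food_db(fd_entry(total = 0, pi = 0, pe = 0, pf = 100)),
    "must be 0"
  )
  expect_error(
    food_db(rbind(fd_entry(), fd_entry())),
    "duplicate"
  )
  expect_error(food_db(fd_entry(racc = 0)), "racc_g")
  fd <- food_db(fd_entry())
  expect_s3_class(fd, "food_db")
})

test_that("pure-fortified foods scale by the DV ratio; I+E can zero fortification", {
  # 6 ug B12 all fortified = 100% of the 6 ug DV; under a 2.4 ug DV the
  # maintained amount is 2.4 with %DV still 100
  fd <- food_db(fd_entry(total = 6, pi = 0, pe = 0, pf = 100))
  mod <- build_modified_fd(fd, dv_current(), dv_updated())
  expect_equal(mod$total_per_100g, 2.4)
  expect_equal(
    percent_dv(mod$total_per_100g, "vit_b12", dv_updated()),
    percent_dv(6, "vit_b12", dv_current())
  )
  # intrinsic 5 + fortified 1: target total 6 * 0.4 = 2.4 < 5, so
  # fortification drops to zero and the food leaves the fortified pool
  fd2 <- food_db(fd_entry(total = 6, pi = 5 / 6 * 100, pe = 0, pf = 1 / 6 * 100))
  mod2 <- build_modified_fd(fd2, dv_current(), dv_updated())
  expect_equal(mod2$total_per_100g, 5)
  expect_equal(mod2$pct_fortified, 0)
  expect_gte(
    percent_dv(mod2$total_per_100g, "vit_b12", dv_updated()),
    percent_dv(6, "vit_b12", dv_current())
  )
})

test_that("frozen nutrients and non-fortified foods pass through unchanged", {
  fd <- toy_fd(
    fd_entry("e1", "vit_e", total = 10, pi = 20, pe = 0, pf = 80),
    fd_entry("fo1", "folate_dfe", total = 300, pi = 10, pe = 40, pf = 50),
    fd_entry("n1", "vit_b12", total = 4, pi = 100, pe = 0, pf = 0)
  )
  mod <- build_modified_fd(fd, dv_current(), dv_updated())
  expect_identical(fd_frame(mod), fd_frame(fd))
  # and a non-fortified food never becomes fortified, even when the DV rises
  fdd <- food_db(fd_entry("d1", "vit_d", total = 3, pi = 100, pe = 0, pf = 0))
  modd <- build_modified_fd(fdd, dv_current(), dv_updated())
  expect_equal(modd$pct_fortified, 0)
  expect_equal(modd$total_per_100g, 3)
})

test_that("rewrite errors when a DV is missing for a fortified nutrient", {
  fd <- food_db(fd_entry())
  tiny <- dv_table(c(vit_d = 10))
  expect_error(build_modified_fd(fd, tiny, tiny), "no Daily Value")
})

rewrite_property_db <- function(seed = 42) {
  cfg <- generator_config(seed = seed)
  generate_food_db(cfg)
}

test_that("rewrite preserves %DV, conserves sources, zeroes exactly at the boundary", {
  fd <- rewrite_property_db()
  mod <- build_modified_fd(fd, dv_current(), dv_updated())
  frozen <- c("vit_e", "folate_dfe")
  src_o <- fortiscope:::source_amounts(fd)
  src_m <- fortiscope:::source_amounts(mod)
  # intrinsic and enriched amounts are never altered (conserved to
  # machine round-off through the percentage re-encoding)
  expect_equal(src_m$intrinsic, src_o$intrinsic, tolerance = 1e-13)
  expect_equal(src_m$enriched, src_o$enriched, tolerance = 1e-13)
  for (i in seq_len(nrow(fd))) {
    n <- fd$nutrient[i]
    if (n %in% frozen || src_o$fortified[i] == 0) {
      expect_identical(mod$total_per_100g[i], fd$total_per_100g[i])
      next
    }
    ratio <- fortiscope:::dv_lookup(dv_updated(), n) /
      fortiscope:::dv_lookup(dv_current(), n)
    ie <- src_o$intrinsic[i] + src_o$enriched[i]
    target <- fd$total_per_100g[i] * ratio
    if (ie >= target) {
      # zeroing case: fortification removed, %DV not below the old one
      expect_identical(src_m$fortified[i], 0)
      expect_gte(
        percent_dv(mod$total_per_100g[i], n, dv_updated()),
        percent_dv(fd$total_per_100g[i], n, dv_current()) - 1e-9
      )
    } else {
      expect_equal(
        percent_dv(mod$total_per_100g[i], n, dv_updated()),
        percent_dv(fd$total_per_100g[i], n, dv_current()),
        tolerance = 1e-9
      )
      expect_gt(src_m$fortified[i], 0)
    }
    # monotonicity of the fortified amount in the DV direction
    if (ratio < 1) expect_lte(src_m$fortified[i], src_o$fortified[i])
    if (ratio > 1) expect_gte(src_m$fortified[i], src_o$fortified[i] - 1e-12)
    # percentage closure after the rewrite
    if (mod$total_per_100g[i] > 0) {
      expect_equal(
        mod$pct_intrinsic[i] + mod$pct_enriched[i] + mod$pct_fortified[i],
        100,
        tolerance = 1e-9
      )
    }
  }
})

test_that("identity DV scenario leaves every entry untouched", {
  fd <- rewrite_property_db(seed = 7)
  mod <- build_modified_fd(fd, dv_current(), dv_same())
  expect_equal(fd_frame(mod), fd_frame(fd), tolerance = 1e-12)
})

test_that("fortified/enriched counts include dual-status foods in both columns", {
  fd <- toy_fd(
    fd_entry("a", "thiamin", total = 1, pi = 20, pe = 40, pf = 40),
    fd_entry("b", "thiamin", total = 1, pi = 60, pe = 40, pf = 0),
    fd_entry("c", "thiamin", total = 1, pi = 100, pe = 0, pf = 0)
  )
  ct <- count_fortified_enriched(fd)
  expect_equal(ct$n_fortified[ct$nutrient == "thiamin"], 1L)
  expect_equal(ct$n_enriched[ct$nutrient == "thiamin"], 2L)
  empty <- count_fortified_enriched(
    food_db(fd_entry()[0, , drop = FALSE])
  )
  expect_true(all(empty$n_fortified == 0L & empty$n_enriched == 0L))
})

test_that("claim counts match exhaustive per-food classification", {
  fd <- rewrite_property_db(seed = 3)
  for (dv in list(dv_current(), dv_updated())) {
    got <- count_claims(fd, dv)
    for (n in unique(fd$nutrient)) {
      sub <- fd[fd$nutrient == n, ]
      pdv <- 100 * (sub$total_per_100g * sub$racc_g / 100) /
        unname(unclass(dv)[n])
      expect_equal(
        got$n_good[got$nutrient == n],
        sum(pdv >= 10 & pdv < 20)
      )
      expect_equal(
        got$n_excellent[got$nutrient == n],
        sum(pdv >= 20)
      )
    }
  }
})

test_that("a food database survives a CSV round trip", {
  fd <- rewrite_property_db(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_db(fd, path)
  back <- read_food_db(path, label = "Original")
  expect_equal(back$total_per_100g, fd$total_per_100g, tolerance = 1e-12)
  expect_equal(back$food_id, fd$food_id)
})
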