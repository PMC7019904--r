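# Small fixtures built in code; no files on disk.

# one-row food database entry, defaults overridable
fd_entry <- function(food_id = "f1", nutrient = "vit_b12",
                     total = 6, pi = 0, pe = 0, pf = 100, racc = 100) {
  data.frame(
    food_id = food_id, nutrient = nutrient, total_per_100g = total,
    pct_intrinsic = pi, pct_enriched = pe, pct_fortified = pf,
    racc_g = racc, stringsAsFactors = FALSE
  )
}

toy_fd <- function(...) food_db(rbind(...))

# plain data.frame view of a food_db, label attribute dropped so two
# databases can be compared on content alone
fd_frame <- function(fd) {
  df <- as.data.frame(fd)
  attr(df, "label") <- NULL
  class(df) <- "data.frame"
  df
}

# balanced two-day intake data from a known person-intercept model on
# the transformed scale; returns data plus the generating parameters
balanced_intake_data <- function(n_persons, lambda = 1, beta0 = 10,
                                 beta_weekend = 0, sd_between = 1,
                                 sd_within = 0.5, seed = 1,
                                 weekend = NULL) {
  set.seed(seed)
  b <- rnorm(n_persons, 0, sd_between)
  if (is.null(weekend)) {
    wk <- matrix(runif(n_persons * 2) < 3 / 7, ncol = 2)
  } else {
    wk <- matrix(weekend, nrow = n_persons, ncol = 2)
  }
  rows <- lapply(1:2, function(d) {
    z <- beta0 + beta_weekend * wk[, d] + b +
      rnorm(n_persons, 0, sd_within)
    data.frame(
      person_id = sprintf("p%04d", seq_len(n_persons)),
      day = d,
      weekend = wk[, d],
      amount = boxcox_inverse(z, lambda),
      stringsAsFactors = FALSE
    )
  })
  list(data = do.call(rbind, rows), b = b)
}

# identity DV scenario: a copy of dv_current() under another label
dv_same <- function(label = "same") {
  v <- as.numeric(dv_current())
  names(v) <- names(dv_current())
  dv_table(v, label)
}

# balanced 2-PSU-per-stratum design with m persons per PSU
balanced_design <- function(n_strata, m = 2) {
  data.frame(
    person_id = sprintf("q%04d", seq_len(n_strata * 2 * m)),
    stratum_id = rep(sprintf("s%02d", seq_len(n_strata)), each = 2 * m),
    psu_id = rep(rep(1:2, each = m), times = n_strata),
    stringsAsFactors = FALSE
  )
}
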