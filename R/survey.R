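#' Combine survey weights across survey cycles
#'
#' When several independent survey cycles are pooled, each person's
#' weight is divided by the number of cycles so the combined sample
#' still sums to one population.
#'
#' @param weights Numeric weights.
#' @param n_cycles Number of pooled cycles (>= 1).
#' @return Adjusted weights.
#' @export
combine_cycle_weights <- function(weights, n_cycles) {
  stopifnot(is.numeric(weights), n_cycles >= 1)
  weights / n_cycles
}

# Sylvester-construction Hadamard matrix of order 2^k
hadamard_sylvester <- function(order) {
  if (order < 1 || bitwAnd(order, order - 1L) != 0) {
    stop("Sylvester construction needs a power-of-two order", call. = FALSE)
  }
  h <- matrix(1, 1, 1)
  while (nrow(h) < order) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

#' Build Balanced Repeated Replication weights
#'
#' For a stratified design with exactly two PSUs per stratum, forms R
#' balanced half-samples from a Sylvester Hadamard matrix of order
#' R = max(4, next power of two >= number of strata) and perturbs the
#' base weights by Fay's coefficient: in each replicate, persons in the
#' selected PSU of a stratum get weight `base * (2 - fay)` and the other
#' PSU gets `base * fay` (classical BRR is `fay = 0`).
#'
#' @param design data.frame with `person_id`, `stratum_id`, `psu_id`.
#' @param base_weights Numeric base weights aligned with `design` rows.
#' @param fay Fay coefficient in [0, 1); default 0.3.
#' @return Object of class `brr_weights`: list with `base_weights`,
#'   `replicate_matrix` (persons x R), `fay`, `design`.
#' @export
build_replicates <- function(design, base_weights, fay = 0.3) {
  stopifnot(
    all(c("person_id", "stratum_id", "psu_id") %in% names(design)),
    length(base_weights) == nrow(design),
    fay >= 0, fay < 1
  )
  strata <- split(design$psu_id, design$stratum_id)
  n_psu <- vapply(strata, function(p) length(unique(p)), integer(1))
  if (any(n_psu != 2L)) {
    bad <- names(strata)[n_psu != 2L]
    stop(
      "BRR requires exactly 2 PSUs per stratum; offending stratum(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  stratum_ids <- names(strata)
  H <- hadamard_sylvester(max(4, next_pow2(length(stratum_ids))))
  R <- nrow(H)

  # first PSU (in sort order) within each stratum is the +1 half-sample
  first_psu <- vapply(
    strata,
    function(p) as.character(sort(unique(p))[1L]), character(1)
  )
  s_idx <- match(as.character(design$stratum_id), stratum_ids)
  is_first <- as.character(design$psu_id) == first_psu[s_idx]

  rep_mat <- matrix(NA_real_, nrow = nrow(design), ncol = R)
  for (r in seq_len(R)) {
    selected <- H[r, s_idx] == 1
    mult <- ifelse(selected == is_first, 2 - fay, fay)
    rep_mat[, r] <- base_weights * mult
  }
  colnames(rep_mat) <- sprintf("rep_%03d", seq_len(R))
  structure(
    list(
      base_weights = base_weights,
      replicate_matrix = rep_mat,
      fay = fay,
      design = design
    ),
    class = "brr_weights"
  )
}

#' @export
print.brr_weights <- function(x, ...) {
  cat(sprintf(
    "BRR replicate weights: %d persons, %d replicates, Fay coefficient %.2f\n",
    nrow(x$replicate_matrix), ncol(x$replicate_matrix), x$fay
  ))
  invisible(x)
}

#' Estimate and BRR standard error of a survey statistic
#'
#' Evaluates `statistic_fn(data, weights)` under the base weights and
#' under every replicate weight set, and returns
#' \deqn{SE = \sqrt{\frac{1}{R(1-fay)^2} \sum_r (\theta_r - \theta)^2}}
#'
#' @param statistic_fn Function of `(data, weights)` returning a scalar.
#' @param data Passed through to `statistic_fn`.
#' @param reps A [build_replicates()] object whose rows align with the
#'   weights `statistic_fn` expects.
#' @return list with `estimate`, `se`, and `replicates` (the per-replicate
#'   statistics).
#' @export
brr_se <- function(statistic_fn, data, reps) {
  stopifnot(inherits(reps, "brr_weights"), is.function(statistic_fn))
  theta <- statistic_fn(data, reps$base_weights)
  if (length(theta) != 1L || !is.numeric(theta)) {
    stop("statistic_fn must return a numeric scalar", call. = FALSE)
  }
  R <- ncol(reps$replicate_matrix)
  if (is.na(theta)) {
    # not-available statistic (e.g. no UL established): no SE either
    return(list(estimate = NA_real_, se = NA_real_, replicates = rep(NA_real_, R)))
  }
  theta_r <- numeric(R)
  for (r in seq_len(R)) {
    val <- tryCatch(
      statistic_fn(data, reps$replicate_matrix[, r]),
      error = function(e) {
        stop("statistic failed on replicate ", r, ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    theta_r[r] <- val
  }
  se <- sqrt(sum((theta_r - theta)^2) / (R * (1 - reps$fay)^2))
  list(estimate = theta, se = se, replicates = theta_r)
}
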