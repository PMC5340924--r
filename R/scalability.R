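#' Loevinger scalability coefficients for polytomous items
#'
#' \eqn{H_{ij} = \mathrm{cov}(X_i, X_j) / \mathrm{cov}_{max}(X_i, X_j)},
#' where the denominator is the largest covariance attainable under the
#' observed marginals — the covariance of the two score vectors after
#' sorting both ascending (comonotonic arrangement). Item coefficients
#' \eqn{H_i} and the scale coefficient pool numerators and denominators
#' over pairs. An item coefficient above 0.3 is taken as evidence of
#' monotonicity.
#'
#' @inheritParams scale_totals
#' @param h_threshold Monotonicity threshold on the item coefficients.
#' @return A list of class `scalability_result`: `item_h` (tibble
#'   `item_id, h`), `scale_h`, `pairwise_h` (tibble `item1, item2, h`),
#'   `monotone` (logical: every item H above threshold).
#' @examples
#' bank <- generate_bank(5, seed = 1)
#' rm <- simulate_responses(bank, rnorm(300), seed = 2)
#' scalability(rm, bank, "scale")$scale_h
#' @export
scalability <- function(responses, bank, scale, h_threshold = 0.3) {
  items <- scale_items(bank, scale)
  if (length(items) < 2) abort("scalability needs >= 2 items")
  m <- response_matrix(responses, items)
  if (nrow(m) < 20) abort("scalability needs >= 20 persons")
  constant <- items[apply(m, 2, function(v) var(v) == 0)]
  if (length(constant) > 0) {
    warn(paste0("constant item(s), H undefined: ",
                paste(constant, collapse = ", ")))
  }
  p <- length(items)
  cov_obs <- cov(m)
  cov_max <- matrix(0, p, p, dimnames = list(items, items))
  sorted <- apply(m, 2, sort)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      cov_max[i, j] <- cov_max[j, i] <- cov(sorted[, i], sorted[, j])
    }
  }
  hij <- ifelse(cov_max > 0, cov_obs / cov_max, NA_real_)
  diag(hij) <- NA_real_
  num_i <- rowSums(cov_obs * upper_lower_mask(p))
  den_i <- rowSums(cov_max)
  item_h <- ifelse(den_i > 0, num_i / den_i, NA_real_)
  off <- upper.tri(cov_obs)
  scale_h <- sum(cov_obs[off]) / sum(cov_max[off])
  idx <- which(off, arr.ind = TRUE)
  structure(list(
    item_h = tibble(item_id = items, h = unname(item_h)),
    scale_h = scale_h,
    pairwise_h = tibble(item1 = items[idx[, 1]], item2 = items[idx[, 2]],
                        h = hij[off]),
    monotone = all(item_h > h_threshold, na.rm = FALSE)
  ), class = "scalability_result")
}

upper_lower_mask <- function(p) {
  m <- matrix(1, p, p)
  diag(m) <- 0
  m
}

#' @export
print.scalability_result <- function(x, ...) {
  cat("Loevinger scalability: scale H =", round(x$scale_h, 3),
      if (isTRUE(x$monotone)) "(all item H > threshold)" else
        "(some item H at or below threshold)", "\n")
  print(x$item_h)
  invisible(x)
}

#' @method tidy scalability_result
#' @export
tidy.scalability_result <- function(x, ...) x$item_h

#' @method glance scalability_result
#' @export
glance.scalability_result <- function(x, ...) {
  tibble(scale_h = x$scale_h, min_item_h = min(x$item_h$h),
         monotone = x$monotone)
}

#' Rest-score trace line of one item
#'
#' Persons are binned by their rest score (scale total minus the item);
#' adjacent rest-score groups are merged greedily from the low end until
#' every bin holds at least `min_group` persons, and the mean item score
#' per bin is reported. Under monotonicity the bin means should be
#' non-decreasing; a decrease larger than 1e-9 between adjacent bins
#' counts as a violation.
#'
#' @inheritParams scale_totals
#' @param item Item id within the scale.
#' @param min_group Minimum persons per bin (default 50).
#' @return A list: `trace` (tibble `bin, rest_min, rest_max, n, mean_item`)
#'   and `n_violations`.
#' @export
rest_score_traces <- function(responses, bank, scale, item, min_group = 50) {
  items <- scale_items(bank, scale)
  if (length(items) < 2) abort("rest-score traces need a scale with >= 2 items")
  if (!item %in% items) abort(paste0("item ", item, " is not in scale ", scale))
  stopifnot(min_group >= 1)
  m <- response_matrix(responses, items)
  x <- m[, item]
  rest <- rowSums(m) - x
  lev <- sort(unique(rest))
  counts <- tabulate(match(rest, lev), nbins = length(lev))
  # greedy merge from the low end
  bin_of <- integer(length(lev))
  b <- 1L
  acc <- 0L
  for (i in seq_along(lev)) {
    bin_of[i] <- b
    acc <- acc + counts[i]
    if (acc >= min_group && i < length(lev)) {
      b <- b + 1L
      acc <- 0L
    }
  }
  # fold a trailing undersized bin into its neighbour
  if (b > 1L && sum(counts[bin_of == b]) < min_group) {
    bin_of[bin_of == b] <- b - 1L
  }
  person_bin <- bin_of[match(rest, lev)]
  trace <- tibble(rest = rest, x = x, bin = person_bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(rest_min = min(.data$rest), rest_max = max(.data$rest),
                     n = dplyr::n(), mean_item = mean(.data$x),
                     .groups = "drop") |>
    dplyr::arrange(.data$rest_min)
  n_violations <- sum(diff(trace$mean_item) < -1e-9)
  list(trace = trace, n_violations = n_violations)
}
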