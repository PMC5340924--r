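# Post-hoc computerized adaptive testing: EAP trait estimation, maximum
# Fisher information item selection, dual stopping rules.

# per-item information at a single theta, vectorized over the bank
bank_information <- function(bank, theta) {
  p1 <- plogis(bank$alpha * (theta - bank$beta1))
  p2 <- plogis(bank$alpha * (theta - bank$beta2))
  d1 <- bank$alpha * p1 * (1 - p1)
  d2 <- bank$alpha * p2 * (1 - p2)
  p <- cbind(1 - p1, p1 - p2, p2)
  d <- cbind(-d1, d1 - d2, d2)
  contrib <- d^2 / pmax(p, .Machine$double.xmin)
  contrib[p <= 0] <- 0
  rowSums(contrib)
}

# list (one per bank row) of Q x 3 log category probability tables
bank_grid_logprobs <- function(bank, nodes) {
  lapply(seq_len(nrow(bank)), function(j) {
    log(pmax(category_probs(bank[j, ], nodes), 1e-300))
  })
}

eap_from_loglik <- function(logL, q) {
  a <- logL + log(q$weights)
  amax <- max(a)
  w <- exp(a - amax)
  w <- w / sum(w)
  theta <- sum(w * q$nodes)
  se <- sqrt(max(sum(w * (q$nodes - theta)^2), 0))
  c(theta = theta, se = se)
}

#' Expected-a-posteriori (EAP) trait estimate
#'
#' Posterior mean and SD of the latent trait under a normal prior and the
#' GRM likelihood of the given responses, computed on a fixed quadrature
#' grid spanning 4.5 prior SDs. With no responses the prior itself is
#' returned (`theta = prior_mean`, `se = prior_sd`), which is what lets a
#' CAT start from theta = 0.
#'
#' @param bank An [item_bank()] (or subset of rows).
#' @param responses Named integer vector of 0/1/2 codes; names are item ids
#'   and must exist in the bank. May be empty.
#' @param prior_mean,prior_sd Normal prior on theta.
#' @param quad_points Number of quadrature nodes.
#' @return A tibble `theta, se, n_items`.
#' @examples
#' bank <- fixture_bank()
#' eap(bank, c(dep33 = 2L, dep35 = 2L))
#' @export
eap <- function(bank, responses, prior_mean = 0, prior_sd = 1,
                quad_points = 61) {
  bank <- item_bank(bank)
  q <- quad_nodes(quad_points, prior_mean, prior_sd)
  if (length(responses) == 0) {
    return(tibble(theta = prior_mean, se = prior_sd, n_items = 0L))
  }
  ids <- names(responses)
  if (is.null(ids) || !all(ids %in% bank$item_id)) {
    abort("responses must be named with item ids present in the bank")
  }
  if (!all(responses %in% 0:2)) abort("response codes must be 0, 1 or 2")
  rows <- match(ids, bank$item_id)
  ord <- order(rows)  # bank order, so sums are reproducible bit-for-bit
  logL <- rep(0, quad_points)
  for (i in ord) {
    lp <- log(pmax(category_probs(bank[rows[i], ], q$nodes), 1e-300))
    logL <- logL + lp[, responses[i] + 1]
  }
  est <- eap_from_loglik(logL, q)
  tibble(theta = est[["theta"]], se = est[["se"]],
         n_items = length(responses))
}

#' EAP scores for a whole cohort
#'
#' Vectorized EAP over every person in a response tibble, using all items
#' of the bank given (subset the bank to a scale first).
#'
#' @inheritParams eap
#' @param responses Tibble with `person_id` plus one column per bank item.
#' @return A tibble `person_id, theta, se`.
#' @export
eap_scores <- function(responses, bank, prior_mean = 0, prior_sd = 1,
                       quad_points = 61) {
  bank <- item_bank(bank)
  m <- response_matrix(responses, bank$item_id)
  q <- quad_nodes(quad_points, prior_mean, prior_sd)
  logp <- bank_grid_logprobs(bank, q$nodes)
  logL <- matrix(0, nrow(m), quad_points)
  for (j in seq_len(nrow(bank))) logL <- logL + t(logp[[j]][, m[, j] + 1])
  a <- sweep(logL, 2, log(q$weights), `+`)
  amax <- apply(a, 1, max)
  w <- exp(a - amax)
  w <- w / rowSums(w)
  theta <- as.vector(w %*% q$nodes)
  se <- sqrt(pmax(as.vector(w %*% q$nodes^2) - theta^2, 0))
  tibble(person_id = responses$person_id, theta = theta, se = se)
}

#' Select the next CAT item by maximum Fisher information
#'
#' Returns the available item with the largest item information at the
#' current trait estimate; ties are broken by the lowest bank row index.
#'
#' @param bank An [item_bank()].
#' @param available Character vector of still-unadministered item ids.
#' @param theta Current trait estimate.
#' @return A single item id.
#' @export
select_next <- function(bank, available, theta) {
  bank <- item_bank(bank)
  if (length(available) == 0) abort("item pool is empty")
  rows <- match(available, bank$item_id)
  if (anyNA(rows)) abort("available contains item ids not in the bank")
  rows <- sort(rows)
  info <- bank_information(bank[rows, ], theta)
  bank$item_id[rows[which.max(info)]]
}

#' Replay one person's responses through the CAT algorithm
#'
#' Post-hoc simulation: the person's complete recorded response vector is
#' given, and the CAT loop looks answers up instead of asking questions.
#' Starting from theta = 0 (the prior mean), the loop selects the most
#' informative remaining item, reveals the recorded answer, re-estimates
#' theta by EAP, and checks the stopping rules after every administered
#' item (minimum one item): first the precision rule (`se <= stop_se`),
#' then the length cap, then pool exhaustion. Everything is deterministic.
#'
#' @inheritParams eap
#' @param full_responses Named integer vector covering every bank item.
#' @param stop_se Precision stopping rule: stop once the EAP standard
#'   error is at or below this value. Use `Inf` to stop after one item and
#'   `0` to force administration of the whole pool.
#' @param max_items Length cap (second stopping rule), or `NULL` for none.
#' @param person_id Carried into the result.
#' @return A list of class `cat_result`: `person_id`, `trace` (tibble
#'   `step, item_id, response, theta, se`), `stop_reason` (one of
#'   `"se_met"`, `"max_items"`, `"pool_exhausted"`), `theta_final`,
#'   `se_final`, `theta_full`, `se_full`, `n_items`.
#' @examples
#' bank <- generate_bank(6, seed = 1)
#' resp <- simulate_responses(bank, 0.5, seed = 2)
#' rec <- setNames(as.integer(resp[1, bank$item_id]), bank$item_id)
#' run_cat(bank, rec, stop_se = 0.5)$stop_reason
#' @export
run_cat <- function(bank, full_responses, stop_se, max_items = NULL,
                    prior_mean = 0, prior_sd = 1, quad_points = 61,
                    person_id = "person") {
  bank <- item_bank(bank)
  if (!all(bank$item_id %in% names(full_responses))) {
    abort("full_responses must cover every bank item (post-hoc simulation)")
  }
  x <- full_responses[bank$item_id]
  if (anyNA(x) || !all(x %in% 0:2)) {
    abort("full_responses must be complete 0/1/2 codes")
  }
  if (!is.null(max_items)) stopifnot(max_items >= 1)
  q <- quad_nodes(quad_points, prior_mean, prior_sd)
  logp <- bank_grid_logprobs(bank, q$nodes)

  J <- nrow(bank)
  available <- seq_len(J)
  administered <- integer(0)
  theta <- prior_mean
  se <- prior_sd
  steps <- list()
  stop_reason <- NULL
  while (TRUE) {
    info <- bank_information(bank[available, , drop = FALSE], theta)
    pick <- available[which.max(info)]
    available <- setdiff(available, pick)
    administered <- sort(c(administered, pick))
    # accumulate in bank order so a full administration reproduces the
    # full-scale estimate bit for bit
    logL <- rep(0, quad_points)
    for (j in administered) logL <- logL + logp[[j]][, x[j] + 1]
    est <- eap_from_loglik(logL, q)
    theta <- est[["theta"]]
    se <- est[["se"]]
    steps[[length(steps) + 1]] <- tibble(
      step = length(steps) + 1L, item_id = bank$item_id[pick],
      response = unname(x[pick]), theta = theta, se = se
    )
    if (se <= stop_se) {
      stop_reason <- "se_met"
    } else if (!is.null(max_items) && length(steps) >= max_items) {
      stop_reason <- "max_items"
    } else if (length(available) == 0) {
      stop_reason <- "pool_exhausted"
    }
    if (!is.null(stop_reason)) break
  }
  # full-scale reference estimate over the whole bank, bank order
  logL_full <- rep(0, quad_points)
  for (j in seq_len(J)) logL_full <- logL_full + logp[[j]][, x[j] + 1]
  full <- eap_from_loglik(logL_full, q)

  structure(list(
    person_id = person_id,
    trace = dplyr::bind_rows(steps),
    stop_reason = stop_reason,
    theta_final = theta, se_final = se,
    theta_full = full[["theta"]], se_full = full[["se"]],
    n_items = length(steps)
  ), class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat("CAT replay for ", x$person_id, ": ", x$n_items, " items, stop = ",
      x$stop_reason, ", theta = ", round(x$theta_final, 3),
      " (full-scale ", round(x$theta_full, 3), ")\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Run the CAT over a whole cohort and summarise efficiency
#'
#' Replays every person's record through [run_cat()] and summarises the
#' number of items administered and the agreement between the CAT trait
#' estimate and the full-scale estimate.
#'
#' @inheritParams run_cat
#' @param responses Complete-case tibble with `person_id` plus one column
#'   per bank item.
#' @return A list of class `cat_sim`: `persons` (tibble `person_id,
#'   n_items, theta_cat, se_cat, theta_full, stop_reason`), `summary`
#'   (tibble `stop_se, max_items, mean_items, sd_items, correlation,
#'   correlation_spearman`), and `results` (list of `cat_result`).
#' @examples
#' bank <- generate_bank(8, seed = 1)
#' rm <- simulate_responses(bank, rnorm(40), seed = 2)
#' simulate_cat(bank, rm, stop_se = 0.45)$summary
#' @export
simulate_cat <- function(bank, responses, stop_se, max_items = NULL,
                         prior_mean = 0, prior_sd = 1, quad_points = 61) {
  bank <- item_bank(bank)
  m <- response_matrix(responses, bank$item_id)
  if (anyNA(m)) abort("simulate_cat requires complete cases")
  results <- purrr::map(seq_len(nrow(m)), function(i) {
    run_cat(bank, m[i, ], stop_se = stop_se, max_items = max_items,
            prior_mean = prior_mean, prior_sd = prior_sd,
            quad_points = quad_points, person_id = responses$person_id[i])
  })
  persons <- purrr::map_dfr(results, function(r) {
    tibble(person_id = r$person_id, n_items = r$n_items,
           theta_cat = r$theta_final, se_cat = r$se_final,
           theta_full = r$theta_full, stop_reason = r$stop_reason)
  })
  summary <- tibble(
    stop_se = stop_se,
    max_items = if (is.null(max_items)) NA_integer_ else as.integer(max_items),
    mean_items = mean(persons$n_items),
    sd_items = sd(persons$n_items),
    correlation = cor(persons$theta_cat, persons$theta_full),
    correlation_spearman = cor(persons$theta_cat, persons$theta_full,
                               method = "spearman")
  )
  structure(list(persons = persons, summary = summary, results = results),
            class = "cat_sim")
}

#' @export
print.cat_sim <- function(x, ...) {
  cat("CAT cohort simulation (n = ", nrow(x$persons), ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method tidy cat_sim
#' @export
tidy.cat_sim <- function(x, ...) x$persons

#' @method glance cat_sim
#' @export
glance.cat_sim <- function(x, ...) x$summary

#' Efficiency table over a grid of precision stopping rules
#'
#' Runs one cohort CAT simulation per standard-error threshold and stacks
#' the summaries: mean/SD items administered and the correlation between
#' CAT and full-scale trait estimates, one row per threshold.
#'
#' @inheritParams simulate_cat
#' @param grid Ascending vector of stop-SE thresholds (default 0.2-0.8 by
#'   0.1, the range inspected when calibrating the precision rule).
#' @return A tibble of class `efficiency_table`, ordered by threshold.
#' @export
se_grid <- function(bank, responses, grid = seq(0.2, 0.8, by = 0.1),
                    max_items = NULL, prior_mean = 0, prior_sd = 1,
                    quad_points = 61) {
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly ascending")
  }
  out <- purrr::map_dfr(grid, function(s) {
    simulate_cat(bank, responses, stop_se = s, max_items = max_items,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 quad_points = quad_points)$summary
  })
  class(out) <- c("efficiency_table", class(out))
  out
}

#' @method autoplot efficiency_table
#' @export
autoplot.efficiency_table <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("mean_items", "correlation"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stop_se, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "stopping rule: SE(theta) threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Reference stopping SE equal to the full scale's precision
#'
#' Computes the cohort mean EAP standard error when every item is
#' administered, then rounds it UP to the nearest grid value, so a CAT
#' stopping at the returned threshold is never allowed to be less precise
#' than the full scale. The unrounded mean is attached as attribute
#' `"unrounded"` and reported via a message.
#'
#' @inheritParams se_grid
#' @return A single grid value, with attribute `unrounded`.
#' @export
full_scale_reference_se <- function(bank, responses,
                                    grid = seq(0.2, 0.8, by = 0.1),
                                    prior_mean = 0, prior_sd = 1,
                                    quad_points = 61) {
  scores <- eap_scores(responses, bank, prior_mean, prior_sd, quad_points)
  m <- mean(scores$se)
  candidates <- grid[grid >= m]
  ref <- if (length(candidates) == 0) {
    warn(paste0("full-scale mean SE ", round(m, 4),
                " exceeds the largest grid value; using max(grid)"))
    max(grid)
  } else {
    min(candidates)
  }
  inform(paste0("full-scale mean EAP SE = ", round(m, 4),
                "; reference stopping SE = ", ref))
  structure(ref, unrounded = m)
}

#' Totals and percent reduction from per-scale mean item counts
#'
#' @param mean_items Per-scale mean numbers of items administered.
#' @param full_lengths Per-scale full lengths.
#' @return A tibble `total_full, total_items, reduction_pct` where
#'   `total_items` is the rounded sum of the means and `reduction_pct`
#'   is `100 (total_full - sum) / total_full` rounded to an integer.
#' @examples
#' reduction_summary(c(6.3, 3.0, 4.9, 7.9), c(16, 6, 12, 16))
#' @export
reduction_summary <- function(mean_items, full_lengths) {
  stopifnot(length(mean_items) == length(full_lengths))
  total_full <- sum(full_lengths)
  total <- sum(mean_items)
  tibble(
    total_full = total_full,
    total_items = round(total),
    reduction_pct = round(100 * (total_full - total) / total_full)
  )
}

#' Combined stopping-rule report over several scales
#'
#' For each scale, finds the reference stopping SE (the grid value
#' matching full-scale precision), runs the CAT with that precision rule
#' alone and with the additional half-length cap, and applies the cap only
#' where it does not drop the CAT/full-scale correlation below
#' `cap_corr_floor` (the cap is counterproductive for a scale whose trait
#' estimates degrade badly under it). Totals and the percent reduction
#' versus the full questionnaire are reported.
#'
#' @param banks Named list of per-scale item banks.
#' @param responses_list Named list of matching complete-case response
#'   tibbles (same names as `banks`).
#' @param grid Stop-SE grid for the reference search.
#' @param cap_corr_floor Minimum acceptable CAT/full correlation under the
#'   cap (default 0.9); below it the scale keeps the precision rule only.
#' @param use_max_items Optional named logical overriding the automatic
#'   cap decision per scale.
#' @inheritParams simulate_cat
#' @return A list of class `cat_report`: `per_scale` (tibble with the
#'   applied rule and efficiency per scale), `totals`
#'   (a [reduction_summary()] row), `reference_se` (named vector).
#' @export
combined_rule_report <- function(banks, responses_list,
                                 grid = seq(0.2, 0.8, by = 0.1),
                                 cap_corr_floor = 0.9,
                                 use_max_items = NULL,
                                 quad_points = 61) {
  stopifnot(identical(sort(names(banks)), sort(names(responses_list))))
  scales <- names(banks)
  refs <- setNames(numeric(length(scales)), scales)
  rows <- purrr::map_dfr(scales, function(sc) {
    bank <- item_bank(banks[[sc]])
    rm <- responses_list[[sc]]
    ref <- full_scale_reference_se(bank, rm, grid, quad_points = quad_points)
    refs[[sc]] <<- as.numeric(ref)
    cap <- floor(nrow(bank) / 2)
    rule1 <- simulate_cat(bank, rm, stop_se = as.numeric(ref),
                          quad_points = quad_points)$summary
    capped <- simulate_cat(bank, rm, stop_se = as.numeric(ref),
                           max_items = cap, quad_points = quad_points)$summary
    apply_cap <- if (!is.null(use_max_items) && sc %in% names(use_max_items)) {
      use_max_items[[sc]]
    } else {
      capped$correlation >= cap_corr_floor
    }
    chosen <- if (apply_cap) capped else rule1
    tibble(
      scale = sc, n_items_full = nrow(bank), stop_se = as.numeric(ref),
      cap_applied = apply_cap, max_items = if (apply_cap) cap else NA_integer_,
      mean_items_rule1 = rule1$mean_items, correlation_rule1 = rule1$correlation,
      mean_items_capped = capped$mean_items, correlation_capped = capped$correlation,
      mean_items = chosen$mean_items, sd_items = chosen$sd_items,
      correlation = chosen$correlation
    )
  })
  structure(list(
    per_scale = rows,
    totals = reduction_summary(rows$mean_items, rows$n_items_full),
    totals_rule1 = reduction_summary(rows$mean_items_rule1, rows$n_items_full),
    reference_se = refs
  ), class = "cat_report")
}

#' @export
print.cat_report <- function(x, ...) {
  cat("Combined stopping-rule CAT report\n")
  print(x$per_scale[c("scale", "stop_se", "cap_applied", "mean_items",
                      "sd_items", "correlation")])
  cat("Precision rule only: ", x$totals_rule1$total_items, "/",
      x$totals_rule1$total_full, " items (", x$totals_rule1$reduction_pct,
      "% reduction)\n", sep = "")
  cat("Combined rules:      ", x$totals$total_items, "/",
      x$totals$total_full, " items (", x$totals$reduction_pct,
      "% reduction)\n", sep = "")
  invisible(x)
}
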