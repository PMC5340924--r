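#' Simulate graded responses from an item bank
#'
#' Each cell is drawn from the GRM category distribution
#' \eqn{P(X = k \mid \theta)} of its item at that person's trait value.
#'
#' @param bank An [item_bank()].
#' @param thetas Either a numeric vector (one trait value per person, used
#'   for every item) or a data frame / matrix with one named column per
#'   scale in the bank (each item uses its own scale's trait).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param person_ids Optional character ids; default `p0001`, `p0002`, ...
#' @return A tibble with `person_id` followed by one integer column
#'   (codes 0/1/2) per bank item, in bank order.
#' @examples
#' bank <- generate_bank(4, seed = 1)
#' simulate_responses(bank, rnorm(10), seed = 2)
#' @export
simulate_responses <- function(bank, thetas, seed = 1L, person_ids = NULL) {
  bank <- item_bank(bank)
  if (is.data.frame(thetas) || is.matrix(thetas)) {
    th <- as.matrix(thetas)
    missing_scales <- setdiff(unique(bank$scale), colnames(th))
    if (length(missing_scales) > 0) {
      abort(paste0("thetas has no column for scale(s): ",
                   paste(missing_scales, collapse = ", ")))
    }
  } else {
    stopifnot(is.numeric(thetas))
    th <- matrix(thetas, ncol = 1,
                 dimnames = list(NULL, unique(bank$scale)[1]))
    if (length(unique(bank$scale)) > 1) {
      th <- th[, rep(1, length(unique(bank$scale))), drop = FALSE]
      colnames(th) <- unique(bank$scale)
    }
  }
  if (any(!is.finite(th))) abort("thetas must be finite")
  n <- nrow(th)
  if (is.null(person_ids)) person_ids <- sprintf("p%04d", seq_len(n))
  with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(bank)), function(j) {
      theta_j <- th[, bank$scale[j]]
      p <- category_probs(bank[j, ], theta_j)
      u <- stats::runif(n)
      # inverse-CDF draw over the 3 ordered categories
      as.integer((u > p[, 1]) + (u > p[, 1] + p[, 2]))
    })
    out <- tibble(person_id = person_ids)
    out[bank$item_id] <- cols
    out
  })
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws per-person latent traits (one per scale, jointly normal with an
#' exchangeable cross-scale correlation), simulates graded responses from
#' the bank, and attaches demographic covariates. Defaults emulate the
#' primary-care sample the fixture bank is modelled on: n = 379 complete
#' responders, 66.8% female, age approximately normal with mean 44.8 and
#' SD 16.5 truncated to 16-87 years.
#'
#' @param bank An [item_bank()]; typically [fixture_bank()].
#' @param n Number of persons.
#' @param trait_cor Exchangeable correlation between scale traits (default
#'   0.6); each trait is marginally standard normal.
#' @param seed Integer seed.
#' @param prob_female Probability that `sex` is 1 (female).
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated).
#' @return A list with `responses` (tibble, `person_id` + item columns),
#'   `covariates` (tibble `person_id, sex, age`), `thetas` (tibble,
#'   `person_id` + one column per scale) and `seed`.
#' @examples
#' cohort <- generate_cohort(fixture_bank(), n = 50, seed = 1)
#' dim(cohort$responses)
#' @export
generate_cohort <- function(bank, n = 379, trait_cor = 0.6, seed = 1L,
                            prob_female = 0.668, age_mean = 44.8,
                            age_sd = 16.5, age_range = c(16, 87)) {
  bank <- item_bank(bank)
  scales <- unique(bank$scale)
  k <- length(scales)
  stopifnot(trait_cor > -1 / max(1, k - 1), trait_cor < 1)
  sigma <- matrix(trait_cor, k, k)
  diag(sigma) <- 1
  with_seed(seed, {
    th <- if (k == 1) matrix(rnorm(n), ncol = 1) else MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
    colnames(th) <- scales
    sex <- stats::rbinom(n, 1, prob_female)
    age <- rnorm(n, age_mean, age_sd)
    age <- pmin(pmax(age, age_range[1]), age_range[2])
    resp_seed <- sample.int(.Machine$integer.max, 1)
    person_ids <- sprintf("p%04d", seq_len(n))
    responses <- simulate_responses(bank, th, seed = resp_seed,
                                    person_ids = person_ids)
    list(
      responses = responses,
      covariates = tibble(person_id = person_ids, sex = sex,
                          age = round(age, 1)),
      thetas = dplyr::bind_cols(tibble(person_id = person_ids),
                                as_tibble(as.data.frame(th))),
      seed = seed
    )
  })
}

#' Generate a two-group cohort with (optional) DIF in one item
#'
#' Builds reference and focal banks with [inject_dif()] and simulates
#' `n_per_group` persons from each, with traits drawn from the same
#' standard-normal distribution so any group difference in responses is
#' item-level DIF, not trait impact.
#'
#' @inheritParams inject_dif
#' @param n_per_group Persons per group.
#' @param seed Integer seed.
#' @return A list with `responses`, `group` (0 = reference, 1 = focal),
#'   `thetas` (true traits) and the two banks.
#' @examples
#' two <- generate_dif_cohort(generate_bank(6, seed = 1), "item03",
#'                            group_shift = -0.8, n_per_group = 100, seed = 2)
#' table(two$group)
#' @export
generate_dif_cohort <- function(bank, item_id, group_shift,
                                slope_ratio = 1, n_per_group = 1000,
                                seed = 1L) {
  pair <- inject_dif(bank, item_id, group_shift, slope_ratio)
  with_seed(seed, {
    th_ref <- rnorm(n_per_group)
    th_foc <- rnorm(n_per_group)
    s1 <- sample.int(.Machine$integer.max, 1)
    s2 <- sample.int(.Machine$integer.max, 1)
    ref <- simulate_responses(pair$reference, th_ref, seed = s1,
                              person_ids = sprintf("r%04d", seq_len(n_per_group)))
    foc <- simulate_responses(pair$focal, th_foc, seed = s2,
                              person_ids = sprintf("f%04d", seq_len(n_per_group)))
    list(
      responses = dplyr::bind_rows(ref, foc),
      group = rep(c(0L, 1L), each = n_per_group),
      thetas = c(th_ref, th_foc),
      reference = pair$reference,
      focal = pair$focal
    )
  })
}
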