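#' @noRd
#' Extract the integer code matrix (persons x items) from a response tibble.
response_matrix <- function(responses, item_ids = NULL) {
  stopifnot(is.data.frame(responses), "person_id" %in% names(responses))
  item_ids <- item_ids %||% setdiff(names(responses), "person_id")
  missing_items <- setdiff(item_ids, names(responses))
  if (length(missing_items) > 0) {
    abort(paste0("response data lack item column(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  m <- as.matrix(responses[item_ids])
  storage.mode(m) <- "integer"
  rownames(m) <- responses$person_id
  m
}

scale_items <- function(bank, scale) {
  bank <- item_bank(bank)
  if (!scale %in% bank$scale) {
    abort(paste0("unknown scale: ", scale, " (bank has: ",
                 paste(unique(bank$scale), collapse = ", "), ")"))
  }
  bank$item_id[bank$scale == scale]
}

#' Recode raw 5-category responses to 0/1/2 scoring
#'
#' Applies the scoring rule for 5-option frequency items: 0 ("no") stays 0,
#' 1 ("sometimes") stays 1, and 2-4 ("regularly", "often", "very often or
#' constantly") collapse to 2. Missing values are preserved. If the data
#' are already on the 0-2 scale (maximum observed code is 2 or less) the
#' recode is skipped and a message is emitted.
#'
#' @param responses Tibble with `person_id` plus integer item columns in
#'   0-4 (or already 0-2); `NA` allowed.
#' @return The recoded tibble, same shape.
#' @examples
#' recode_raw(tibble::tibble(person_id = "p1", a = 3L, b = 0L))
#' @export
recode_raw <- function(responses) {
  items <- setdiff(names(responses), "person_id")
  m <- as.matrix(responses[items])
  bad <- which(!is.na(m) & (m < 0 | m > 4 | m != floor(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(head(bad, 5), 1, function(ij) {
      paste0("person ", responses$person_id[ij[1]], ", item ", items[ij[2]],
             " (code ", m[ij[1], ij[2]], ")")
    })
    abort(paste0("raw codes must be integers in 0-4; offending cell(s): ",
                 paste(cells, collapse = "; ")))
  }
  if (max(m, na.rm = TRUE) <= 2) {
    inform("responses already on the 0-2 scale; recode skipped")
    return(responses)
  }
  m[!is.na(m) & m >= 2] <- 2L
  out <- responses
  out[items] <- as.data.frame(m)
  out
}

#' Complete-case filtering
#'
#' Drops every person with at least one missing item response, mirroring a
#' complete-case analysis, and reports who was excluded and the retention
#' percentage (to one decimal).
#'
#' @param responses Tibble with `person_id` plus item columns.
#' @return A list with `responses` (filtered tibble), `excluded`
#'   (character vector of dropped person ids) and `retention_pct`.
#' @examples
#' rm <- tibble::tibble(person_id = c("a", "b"), x = c(1L, NA), y = c(0L, 2L))
#' complete_cases(rm)$retention_pct
#' @export
complete_cases <- function(responses) {
  keep <- complete.cases(responses[setdiff(names(responses), "person_id")])
  if (!any(keep)) {
    abort("complete-case filtering removed every person")
  }
  list(
    responses = responses[keep, , drop = FALSE],
    excluded = responses$person_id[!keep],
    retention_pct = round(100 * sum(keep) / length(keep), 1)
  )
}

#' Per-person scale totals
#'
#' Sums the 0/1/2 item codes over one scale's items, giving the classical
#' total score with range 0 to twice the number of items.
#'
#' @param responses Complete-case response tibble.
#' @param bank An [item_bank()] providing the item-to-scale map.
#' @param scale Scale name.
#' @return A tibble `person_id, total`.
#' @export
scale_totals <- function(responses, bank, scale) {
  m <- response_matrix(responses, scale_items(bank, scale))
  tibble(person_id = responses$person_id, total = as.integer(rowSums(m)))
}

#' Cronbach alpha of a scale
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} with `k` items, sample
#' variances (denominator n-1), and \eqn{s_T^2} the variance of the total.
#'
#' @inheritParams scale_totals
#' @return A single numeric value.
#' @export
cronbach_alpha <- function(responses, bank, scale) {
  m <- response_matrix(responses, scale_items(bank, scale))
  cronbach_alpha_matrix(m)
}

cronbach_alpha_matrix <- function(m) {
  k <- ncol(m)
  if (k < 2) abort("Cronbach alpha needs at least 2 items")
  if (nrow(m) < 2) abort("Cronbach alpha needs at least 2 persons")
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    abort("total score has zero variance; alpha undefined")
  }
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Alpha if item deleted
#'
#' Cronbach alpha of the scale recomputed with each item removed in turn;
#' an item whose removal raises alpha is pulling internal consistency down.
#'
#' @inheritParams scale_totals
#' @return A tibble `item_id, alpha` with one row per scale item.
#' @export
alpha_if_deleted <- function(responses, bank, scale) {
  items <- scale_items(bank, scale)
  if (length(items) < 3) {
    abort("alpha-if-deleted needs at least 3 items")
  }
  m <- response_matrix(responses, items)
  tibble(
    item_id = items,
    alpha = purrr::map_dbl(seq_along(items),
                           function(j) cronbach_alpha_matrix(m[, -j, drop = FALSE]))
  )
}

#' Per-scale descriptive summary
#'
#' Classical summary of each scale's total score: mean, standard error of
#' the mean (SD/sqrt(n), n-1 denominator), median, observed range, and
#' Cronbach alpha.
#'
#' @inheritParams scale_totals
#' @param scales Scales to summarise; default all scales in the bank.
#' @return A tibble with one row per scale.
#' @examples
#' cohort <- generate_cohort(fixture_bank(), n = 60, seed = 1)
#' describe_scales(cohort$responses, fixture_bank())
#' @export
describe_scales <- function(responses, bank, scales = NULL) {
  bank <- item_bank(bank)
  scales <- scales %||% unique(bank$scale)
  purrr::map_dfr(scales, function(sc) {
    tot <- scale_totals(responses, bank, sc)$total
    tibble(
      scale = sc,
      n = length(tot),
      n_items = length(scale_items(bank, sc)),
      mean_total = mean(tot),
      se_mean = sd(tot) / sqrt(length(tot)),
      median = median(tot),
      min = min(tot),
      max = max(tot),
      cronbach_alpha = cronbach_alpha(responses, bank, sc)
    )
  })
}
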