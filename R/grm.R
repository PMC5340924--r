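#' Graded response model probabilities
#'
#' The GRM for a three-category item is defined through two boundary curves
#' \deqn{P^*_k(\theta) = \mathrm{logistic}(\alpha(\theta - \beta_k)), k = 1, 2,}
#' the probabilities of scoring at least 1 and at least 2. Category
#' probabilities are adjacent differences: \eqn{P_0 = 1 - P^*_1},
#' \eqn{P_1 = P^*_1 - P^*_2}, \eqn{P_2 = P^*_2}. Logistic slopes are used
#' as-is, without the 1.7 normal-ogive scaling constant.
#'
#' @param item A single bank row (or any list with `alpha`, `beta1`, `beta2`).
#' @param k Boundary index, 1 or 2.
#' @param theta Numeric vector of trait values.
#' @return `boundary_prob()`: numeric vector of boundary probabilities.
#'   `category_probs()`: a numeric matrix, `length(theta)` rows by 3 columns
#'   `p0, p1, p2`, each row summing to one.
#' @examples
#' it <- list(alpha = 2.457, beta1 = 0.119, beta2 = 0.828)
#' boundary_prob(it, 1, theta = 0.119)  # 0.5 at theta = beta1
#' category_probs(it, c(-2, 0, 2))
#' @export
boundary_prob <- function(item, k, theta) {
  stopifnot(k %in% c(1, 2))
  beta <- if (k == 1) item$beta1 else item$beta2
  plogis(item$alpha * (theta - beta))
}

#' @rdname boundary_prob
#' @export
category_probs <- function(item, theta) {
  p1 <- boundary_prob(item, 1, theta)
  p2 <- boundary_prob(item, 2, theta)
  cbind(p0 = 1 - p1, p1 = p1 - p2, p2 = p2)
}

#' Fisher information of an item or bank at a trait value
#'
#' Item information for the 3-category GRM distribution,
#' \eqn{I(\theta) = \sum_k (dP_k/d\theta)^2 / P_k}, with boundary-curve
#' derivatives \eqn{dP^*_k/d\theta = \alpha P^*_k (1 - P^*_k)}. Test
#' information is the sum over items; the standard error of the trait is
#' `1 / sqrt(information)`.
#'
#' @inheritParams boundary_prob
#' @param bank An [item_bank()] (any subset of rows).
#' @param info Nonnegative information value(s).
#' @return Numeric vector the length of `theta`.
#' @examples
#' it <- list(alpha = 7.377, beta1 = 0.688, beta2 = 1.349)
#' item_information(it, seq(-2, 2, 0.5))
#' @export
item_information <- function(item, theta) {
  p1 <- boundary_prob(item, 1, theta)
  p2 <- boundary_prob(item, 2, theta)
  d1 <- item$alpha * p1 * (1 - p1)
  d2 <- item$alpha * p2 * (1 - p2)
  p <- cbind(1 - p1, p1 - p2, p2)
  d <- cbind(-d1, d1 - d2, d2)
  contrib <- d^2 / pmax(p, .Machine$double.xmin)
  contrib[p <= 0] <- 0
  rowSums(contrib)
}

#' @rdname item_information
#' @export
test_information <- function(bank, theta) {
  bank <- as_tibble(bank)
  if (nrow(bank) == 0) return(rep(0, length(theta)))
  Reduce(`+`, purrr::map(seq_len(nrow(bank)),
                         function(j) item_information(bank[j, ], theta)))
}

#' @rdname item_information
#' @export
se_from_information <- function(info) {
  ifelse(info > 0, 1 / sqrt(info), Inf)
}

#' Category response curves and CRC anomaly detection
#'
#' `crc_table()` tabulates the category probabilities of one item over a
#' theta grid (one row per grid point). `detect_crc_anomaly()` flags the
#' pattern where the middle category ("sometimes") is never the modal
#' response at any trait level — the shape reported for items whose
#' thresholds nearly coincide, suggesting responders cannot separate the
#' middle from an adjacent category.
#'
#' @inheritParams boundary_prob
#' @param theta_grid Sorted numeric grid with at least 3 points spanning
#'   at least \[-4, 4\].
#' @param item_id Optional id carried into the output.
#' @return `crc_table()`: a tibble with class `crc_table` and columns
#'   `item_id, theta, category, prob`. `detect_crc_anomaly()`: logical.
#' @examples
#' tab <- crc_table(list(alpha = 2, beta1 = -1, beta2 = 2), seq(-4, 4, 0.1))
#' detect_crc_anomaly(list(alpha = 1, beta1 = 0, beta2 = 0.05), seq(-4, 4, 0.01))
#' @export
crc_table <- function(item, theta_grid = seq(-4, 4, by = 0.05),
                      item_id = NULL) {
  check_theta_grid(theta_grid)
  p <- category_probs(item, theta_grid)
  id <- item_id %||% (if (!is.null(item$item_id)) item$item_id else "item")
  out <- tibble(
    item_id = id,
    theta = rep(theta_grid, times = 3),
    category = rep(0:2, each = length(theta_grid)),
    prob = c(p[, 1], p[, 2], p[, 3])
  )
  class(out) <- c("crc_table", class(out))
  out
}

check_theta_grid <- function(theta_grid) {
  if (length(theta_grid) < 3 || is.unsorted(theta_grid)) {
    abort("theta_grid must be sorted with at least 3 points")
  }
  if (theta_grid[1] > -4 || theta_grid[length(theta_grid)] < 4) {
    abort("theta_grid must span at least [-4, 4]")
  }
  invisible(theta_grid)
}

#' @rdname crc_table
#' @export
detect_crc_anomaly <- function(item, theta_grid = seq(-4, 4, by = 0.01)) {
  check_theta_grid(theta_grid)
  p <- category_probs(item, theta_grid)
  !any(max.col(p) == 2)
}

#' Plot category response curves
#'
#' @param object A `crc_table` from [crc_table()] (tables for several items
#'   can be row-bound and are facetted by item).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_table
#' @export
autoplot.crc_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$prob,
                                       colour = factor(.data$category))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$item_id)) +
    ggplot2::labs(x = expression(theta), y = "Pr(response)",
                  colour = "category") +
    ggplot2::theme_minimal()
}
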