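# Differential item functioning via nested cumulative-logit regressions.
# M1: response ~ theta; M2: + group; M3: + theta x group. The effect-size
# criterion is the McFadden pseudo R-squared change between nested models;
# an item is flagged when the change reaches 0.03 AND the likelihood-ratio
# test is significant at .01 (a "significant and relevant" two-part rule).

polr_loglik <- function(formula, data) {
  # tight optimizer tolerance so nested-model likelihood differences are
  # stable to ~1e-8 (e.g. invariant under relabelling the groups);
  # warnings from polr's internal starting-value glm are uninformative here
  fit <- suppressWarnings(
    MASS::polr(formula, data = data, Hess = FALSE,
               control = list(reltol = 1e-12, maxit = 500))
  )
  as.numeric(logLik(fit))
}

#' DIF screen for a single item
#'
#' Fits the three nested ordinal logistic models by maximum likelihood and
#' reports McFadden pseudo-R-squared changes (uniform: adding the group
#' main effect; non-uniform: adding the trait-by-group interaction) with
#' likelihood-ratio p values. `flagged` is `TRUE` when either change is at
#' least `r2_criterion` and its LR p value is below `p_criterion`.
#'
#' @param item Integer vector of 0/1/2 responses.
#' @param theta Numeric trait estimates (matching criterion).
#' @param group 0/1 group indicator; both groups need >= 20 persons.
#' @param item_id,covariate Labels carried into the result row.
#' @param r2_criterion Pseudo-R-squared change criterion (default 0.03).
#' @param p_criterion LR-test significance criterion (default 0.01).
#' @return A one-row tibble: `item_id, covariate, r2_uniform,
#'   r2_nonuniform, lr_p_uniform, lr_p_nonuniform, flagged, error`
#'   (`error` is `NA` unless a model failed, in which case the statistics
#'   are `NA` and `flagged` is `NA`).
#' @examples
#' th <- rnorm(200)
#' y <- as.integer(cut(th + rnorm(200), c(-Inf, 0, 1, Inf))) - 1L
#' ordinal_dif(y, th, rep(0:1, 100))
#' @export
ordinal_dif <- function(item, theta, group, item_id = "item",
                        covariate = "group", r2_criterion = 0.03,
                        p_criterion = 0.01) {
  stopifnot(length(item) == length(theta), length(item) == length(group))
  if (!all(group %in% 0:1)) abort("group must be coded 0/1")
  if (min(table(factor(group, levels = 0:1))) < 20) {
    abort("each group needs at least 20 persons")
  }
  if (any(!is.finite(theta))) abort("theta must be finite")
  d <- data.frame(y = factor(item, ordered = TRUE), theta = theta,
                  group = group)
  d$y <- droplevels(d$y)
  row <- tibble(item_id = item_id, covariate = covariate,
                r2_uniform = NA_real_, r2_nonuniform = NA_real_,
                lr_p_uniform = NA_real_, lr_p_nonuniform = NA_real_,
                flagged = NA, error = NA_character_)
  if (nlevels(d$y) < 2) {
    row$error <- "item response is constant"
    return(row)
  }
  ll <- tryCatch(
    list(
      m0 = polr_loglik(y ~ 1, d),
      m1 = polr_loglik(y ~ theta, d),
      m2 = polr_loglik(y ~ theta + group, d),
      m3 = polr_loglik(y ~ theta * group, d)
    ),
    error = function(e) conditionMessage(e)
  )
  if (is.character(ll)) {
    row$error <- ll
    return(row)
  }
  r2 <- function(l) 1 - l / ll$m0
  row$r2_uniform <- max(r2(ll$m2) - r2(ll$m1), 0)
  row$r2_nonuniform <- max(r2(ll$m3) - r2(ll$m2), 0)
  row$lr_p_uniform <- pchisq(2 * max(ll$m2 - ll$m1, 0), df = 1,
                             lower.tail = FALSE)
  row$lr_p_nonuniform <- pchisq(2 * max(ll$m3 - ll$m2, 0), df = 1,
                                lower.tail = FALSE)
  row$flagged <-
    (row$r2_uniform >= r2_criterion && row$lr_p_uniform < p_criterion) ||
    (row$r2_nonuniform >= r2_criterion && row$lr_p_nonuniform < p_criterion)
  row
}

#' DIF screen across items and covariates
#'
#' For every scale in the bank, computes per-person EAP trait estimates
#' from all of that scale's items, then runs [ordinal_dif()] for each item
#' against each covariate: `sex` as given (0/1) and, when present, `age`
#' dichotomized at the sample median.
#'
#' @inheritParams scale_totals
#' @param covariates Tibble `person_id, sex` and optionally `age`.
#' @param r2_criterion,p_criterion Flagging rule; see [ordinal_dif()].
#' @param quad_points Quadrature nodes for the EAP trait estimates.
#' @return A tibble with one row per item x covariate (columns as in
#'   [ordinal_dif()], plus `scale`); per-item failures are reported in the
#'   `error` column, never aborting the screen.
#' @export
dif_screen <- function(responses, bank, covariates, r2_criterion = 0.03,
                       p_criterion = 0.01, quad_points = 61) {
  bank <- item_bank(bank)
  if (!all(c("person_id", "sex") %in% names(covariates))) {
    abort("covariates must contain person_id and sex")
  }
  cov <- covariates[match(responses$person_id, covariates$person_id), ]
  if (anyNA(cov$sex)) abort("covariates missing for some persons")
  groups <- list(sex = as.integer(cov$sex))
  if ("age" %in% names(covariates)) {
    groups$age <- as.integer(cov$age > median(cov$age))
  }
  purrr::map_dfr(unique(bank$scale), function(sc) {
    sub_bank <- bank[bank$scale == sc, ]
    th <- eap_scores(responses, sub_bank, quad_points = quad_points)$theta
    purrr::map_dfr(sub_bank$item_id, function(id) {
      x <- responses[[id]]
      purrr::map_dfr(names(groups), function(g) {
        res <- tryCatch(
          ordinal_dif(x, th, groups[[g]], item_id = id, covariate = g,
                      r2_criterion = r2_criterion,
                      p_criterion = p_criterion),
          error = function(e) {
            tibble(item_id = id, covariate = g, r2_uniform = NA_real_,
                   r2_nonuniform = NA_real_, lr_p_uniform = NA_real_,
                   lr_p_nonuniform = NA_real_, flagged = NA,
                   error = conditionMessage(e))
          }
        )
        dplyr::mutate(res, scale = sc, .before = 1)
      })
    })
  })
}
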