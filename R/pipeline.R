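#' Run the five-stage psychometric pipeline
#'
#' Executes, per scale: (1) recoding, complete-case filtering and
#' descriptives with Cronbach alpha; (2) IRT assumption checks —
#' polychoric one-factor fit indices, residual-correlation
#' local-dependence flags, Loevinger scalability; (3) GRM marginal ML
#' calibration with CRC anomaly detection; (4) DIF screening against the
#' covariates (when supplied); (5) the post-hoc CAT simulation — SE-grid
#' efficiency table, full-scale reference SE, and the combined
#' stopping-rule report. Stage failures are caught and recorded so later,
#' independent stages still run; stages 4 and 5 depend on stage 3's
#' calibrated bank.
#'
#' @param responses Response tibble (raw 0-4 or coded 0-2), or a file path.
#' @param scale_def An [item_bank()] or bank file path; only `item_id` and
#'   `scale` are used to define the scales — all parameters are
#'   re-estimated from the data in stage 3.
#' @param covariates Optional covariate tibble or path (`person_id, sex[,
#'   age]`); without it stage 4 is skipped.
#' @param thresholds Named list: `residual` (local dependence, 0.2),
#'   `scalability` (0.3), `dif_r2` (0.03), `dif_p` (0.01).
#' @param se_grid_values Stop-SE grid for stage 5.
#' @param cap_corr_floor Passed to [combined_rule_report()].
#' @param outdir Optional directory; when given, each stage writes its
#'   table(s) as CSV.
#' @param quad_points Quadrature nodes used in stages 3-5.
#' @return A list of class `pipeline_result` with elements `descriptives`,
#'   `assumptions`, `calibration` (list of `grm_fit`), `calibrated_bank`,
#'   `crc_anomalies`, `dif`, `cat` (efficiency tables + `cat_report`),
#'   `retention`, `errors` (named list of stage failures).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(fixture_bank(), n = 150, seed = 1)
#' res <- run_pipeline(cohort$responses, fixture_bank(),
#'                     covariates = cohort$covariates)
#' res$descriptives
#' }
#' @export
run_pipeline <- function(responses, scale_def, covariates = NULL,
                         thresholds = list(), se_grid_values = seq(0.2, 0.8, by = 0.1),
                         cap_corr_floor = 0.9, outdir = NULL,
                         quad_points = 61) {
  thr <- utils::modifyList(
    list(residual = 0.2, scalability = 0.3, dif_r2 = 0.03, dif_p = 0.01),
    thresholds
  )
  if (is.character(responses)) responses <- read_responses(responses)
  if (is.character(scale_def)) scale_def <- read_bank(scale_def)
  bank0 <- item_bank(scale_def)
  if (is.character(covariates)) covariates <- read_covariates(covariates)
  missing_items <- setdiff(bank0$item_id, names(responses))
  if (length(missing_items) > 0) {
    abort(paste0("configured scale items missing from responses: ",
                 paste(missing_items, collapse = ", ")))
  }
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  out <- list(errors = list())
  scales <- unique(bank0$scale)

  # Stage 1 -- descriptives
  m <- as.matrix(responses[bank0$item_id])
  if (max(m, na.rm = TRUE) > 2) responses <- recode_raw(responses)
  cc <- complete_cases(responses)
  rm <- cc$responses
  out$retention <- tibble(n_total = nrow(responses),
                          n_complete = nrow(rm),
                          retention_pct = cc$retention_pct,
                          excluded = list(cc$excluded))
  out$descriptives <- tryCatch({
    d <- describe_scales(rm, bank0)
    aid <- purrr::map_dfr(scales, function(sc) {
      dplyr::mutate(alpha_if_deleted(rm, bank0, sc), scale = sc, .before = 1)
    })
    list(summary = d, alpha_if_deleted = aid)
  }, error = function(e) note("descriptives", e))

  # Stage 2 -- IRT assumptions
  out$assumptions <- tryCatch({
    purrr::map(setNames(scales, scales), function(sc) {
      pc <- polychoric_matrix(rm, bank0, sc)
      fit <- fit_one_factor(pc, n = nrow(rm))
      list(
        fit = fit$fit,
        local_dependence = flag_local_dependence(fit$residuals,
                                                 threshold = thr$residual),
        scalability = scalability(rm, bank0, sc, h_threshold = thr$scalability)
      )
    })
  }, error = function(e) note("assumptions", e))
  out$pair_count <- count_item_pairs(table(bank0$scale))

  # Stage 3 -- GRM calibration
  out$calibration <- tryCatch({
    purrr::map(setNames(scales, scales), function(sc) {
      fit_grm_mml(rm, bank0, sc, quad_points = quad_points)
    })
  }, error = function(e) note("calibration", e))
  if (!is.null(out$calibration)) {
    out$calibrated_bank <- item_bank(
      dplyr::bind_rows(purrr::map(out$calibration, "bank"))[
        , c("item_id", "scale", "alpha", "beta1", "beta2")]
    )
    out$crc_anomalies <- purrr::map_dfr(
      seq_len(nrow(out$calibrated_bank)), function(j) {
        row <- out$calibrated_bank[j, ]
        tibble(item_id = row$item_id, scale = row$scale,
               crc_anomaly = detect_crc_anomaly(row))
      })
  }

  # Stage 4 -- DIF (needs calibration + covariates)
  if (!is.null(covariates) && !is.null(out$calibration)) {
    out$dif <- tryCatch(
      dif_screen(rm, out$calibrated_bank, covariates,
                 r2_criterion = thr$dif_r2, p_criterion = thr$dif_p,
                 quad_points = quad_points),
      error = function(e) note("dif", e)
    )
  }

  # Stage 5 -- CAT simulation
  if (!is.null(out$calibration)) {
    out$cat <- tryCatch({
      banks <- purrr::map(setNames(scales, scales), function(sc) {
        out$calibrated_bank[out$calibrated_bank$scale == sc, ]
      })
      rms <- purrr::map(banks, function(b) {
        rm[c("person_id", b$item_id)]
      })
      grids <- purrr::map(setNames(scales, scales), function(sc) {
        se_grid(banks[[sc]], rms[[sc]], grid = se_grid_values,
                quad_points = quad_points)
      })
      report <- combined_rule_report(banks, rms, grid = se_grid_values,
                                     cap_corr_floor = cap_corr_floor,
                                     quad_points = quad_points)
      list(efficiency = grids, report = report)
    }, error = function(e) note("cat", e))
  }

  out$errors <- errors
  class(out) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_artifacts(out, outdir)
  out
}

write_pipeline_artifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(outdir, name))
  }
  w(dplyr::select(out$retention, -"excluded"), "retention.csv")
  if (!is.null(out$descriptives)) {
    w(out$descriptives$summary, "descriptives.csv")
    w(out$descriptives$alpha_if_deleted, "alpha_if_deleted.csv")
  }
  if (!is.null(out$assumptions)) {
    w(purrr::map_dfr(names(out$assumptions), function(sc) {
      dplyr::mutate(out$assumptions[[sc]]$fit, scale = sc, .before = 1)
    }), "fit_indices.csv")
    w(purrr::map_dfr(names(out$assumptions), function(sc) {
      dplyr::mutate(out$assumptions[[sc]]$local_dependence, scale = sc,
                    .before = 1)
    }), "local_dependence.csv")
    w(purrr::map_dfr(names(out$assumptions), function(sc) {
      dplyr::mutate(out$assumptions[[sc]]$scalability$item_h, scale = sc,
                    .before = 1)
    }), "scalability.csv")
  }
  if (!is.null(out$calibrated_bank)) {
    write_bank(out$calibrated_bank, file.path(outdir, "calibrated_bank.csv"))
    w(out$crc_anomalies, "crc_anomalies.csv")
  }
  if (!is.null(out$dif) && is.data.frame(out$dif)) w(out$dif, "dif.csv")
  if (!is.null(out$cat)) {
    w(purrr::map_dfr(names(out$cat$efficiency), function(sc) {
      dplyr::mutate(as_tibble(out$cat$efficiency[[sc]]), scale = sc,
                    .before = 1)
    }), "cat_efficiency.csv")
    w(out$cat$report$per_scale, "cat_report.csv")
    w(out$cat$report$totals, "cat_totals.csv")
  }
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Psychometric pipeline result\n")
  cat("Retention:", x$retention$n_complete, "/", x$retention$n_total,
      paste0("(", x$retention$retention_pct, "%)\n"))
  if (!is.null(x$descriptives)) print(x$descriptives$summary)
  if (!is.null(x$cat)) print(x$cat$report)
  if (length(x$errors) > 0) {
    cat("Stage errors:\n")
    for (s in names(x$errors)) cat(" -", s, ":", x$errors[[s]], "\n")
  }
  invisible(x)
}
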