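#' Construct and validate an item bank
#'
#' An item bank is a tibble with one row per item and the calibrated graded
#' response model (GRM) parameters: a discrimination (slope) `alpha` and two
#' ordered thresholds `beta1 < beta2` on the latent-trait (theta) scale.
#' Three response categories (0/1/2) are assumed throughout the package, so
#' two thresholds fully describe an item.
#'
#' @param x A data frame with columns `item_id` (character, unique), `scale`
#'   (character), `alpha` (positive), `beta1`, `beta2` (finite, `beta1 < beta2`).
#' @return A validated tibble with those columns, in the input row order.
#' @examples
#' item_bank(data.frame(item_id = "a", scale = "s", alpha = 2,
#'                      beta1 = -0.5, beta2 = 0.5))
#' @export
item_bank <- function(x) {
  x <- as_tibble(x)
  needed <- c("item_id", "scale", "alpha", "beta1", "beta2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("item bank is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$item_id <- as.character(x$item_id)
  x$scale <- as.character(x$scale)
  if (anyDuplicated(x$item_id)) {
    abort(paste0("duplicated item_id in bank: ",
                 paste(unique(x$item_id[duplicated(x$item_id)]), collapse = ", ")))
  }
  bad <- which(!is.finite(x$alpha) | x$alpha <= 0)
  if (length(bad) > 0) {
    abort(paste0("alpha must be positive and finite; offending item(s): ",
                 paste(x$item_id[bad], collapse = ", ")))
  }
  bad <- which(!is.finite(x$beta1) | !is.finite(x$beta2) | x$beta1 >= x$beta2)
  if (length(bad) > 0) {
    abort(paste0("thresholds must be finite with beta1 < beta2; offending item(s): ",
                 paste(x$item_id[bad], collapse = ", ")))
  }
  dplyr::select(x, dplyr::all_of(needed), dplyr::everything())
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random item bank
#'
#' Draws item parameters uniformly from the given ranges. Threshold ordering
#' is guaranteed by construction: `beta2 = beta1 + spacing` with a positive
#' spacing. The draw is fully determined by `seed`.
#'
#' @param n_items Number of items (positive integer).
#' @param alpha_range Length-2 numeric, lower bound strictly positive.
#' @param beta1_range Length-2 numeric range for the first threshold.
#' @param spacing_range Length-2 positive numeric range for `beta2 - beta1`.
#' @param seed Integer seed.
#' @param scale Scale name assigned to every generated item.
#' @param prefix Item-id prefix; ids are `<prefix><number>`.
#' @return An [item_bank()] tibble with `n_items` rows.
#' @examples
#' generate_bank(6, seed = 1)
#' @export
generate_bank <- function(n_items,
                          alpha_range = c(1, 3.5),
                          beta1_range = c(-1, 1),
                          spacing_range = c(0.5, 1.5),
                          seed = 1L,
                          scale = "scale",
                          prefix = "item") {
  stopifnot(length(n_items) == 1, n_items >= 1)
  if (alpha_range[1] <= 0) {
    abort("alpha_range lower bound must be strictly positive")
  }
  if (spacing_range[1] <= 0) {
    abort("spacing_range must be strictly positive")
  }
  with_seed(seed, {
    alpha <- stats::runif(n_items, alpha_range[1], alpha_range[2])
    beta1 <- stats::runif(n_items, beta1_range[1], beta1_range[2])
    spacing <- stats::runif(n_items, spacing_range[1], spacing_range[2])
    item_bank(tibble(
      item_id = sprintf("%s%02d", prefix, seq_len(n_items)),
      scale = scale,
      alpha = alpha,
      beta1 = beta1,
      beta2 = beta1 + spacing
    ))
  })
}

# 4DSQ item-to-scale layout: somatization 1-16, distress/depression/anxiety
# interleaved over 17-50 (16/6/12 items).
fixture_layout <- function() {
  list(
    somatization = 1:16,
    distress = c(17, 19, 20, 22, 25, 29, 31, 32, 34, 36, 37, 39, 41, 44, 47, 48),
    depression = c(28, 30, 33, 35, 38, 46),
    anxiety = c(18, 21, 23, 24, 26, 27, 40, 42, 43, 45, 49, 50)
  )
}

scale_prefixes <- c(distress = "dis", depression = "dep",
                    anxiety = "anx", somatization = "som")

#' Fixture item bank for a four-scale, 50-item questionnaire
#'
#' Returns a 50-item bank with the 4DSQ scale structure (16 distress, 6
#' depression, 12 anxiety, 16 somatization items, all scored 0/1/2). Five
#' items carry published parameter values: the depression items `dep33`
#' (alpha 7.377, beta1 0.688, beta2 1.349) and `dep35` (alpha 2.457, beta1
#' 0.119, beta2 0.828) carry full parameter sets, and `dis37` (alpha 3.483),
#' `anx27` (alpha 5.527) and `som16` (alpha 1.855) carry their reported
#' discriminations. All remaining parameters are filler values drawn once
#' from a fixed seed (alpha in \[1, 3.5\], beta1 in \[-1, 1\], spacing in
#' \[0.5, 1.5\]), so the bank is identical across calls and versions.
#'
#' @return An [item_bank()] tibble with 50 rows.
#' @examples
#' bank <- fixture_bank()
#' dplyr::count(bank, scale)
#' @export
fixture_bank <- function() {
  layout <- fixture_layout()
  rows <- purrr::imap(layout, function(nums, sc) {
    tibble(item_id = sprintf("%s%02d", scale_prefixes[[sc]], nums),
           scale = sc, number = nums)
  })
  bank <- dplyr::arrange(dplyr::bind_rows(rows), .data$number)
  n <- nrow(bank)
  filler <- with_seed(20170221L, {
    tibble(
      alpha = stats::runif(n, 1, 3.5),
      beta1 = stats::runif(n, -1, 1),
      spacing = stats::runif(n, 0.5, 1.5)
    )
  })
  bank$alpha <- filler$alpha
  bank$beta1 <- filler$beta1
  bank$beta2 <- filler$beta1 + filler$spacing
  fix <- function(id, alpha = NULL, beta1 = NULL, beta2 = NULL) {
    i <- match(id, bank$item_id)
    if (!is.null(alpha)) bank$alpha[i] <<- alpha
    if (!is.null(beta1)) bank$beta1[i] <<- beta1
    if (!is.null(beta2)) bank$beta2[i] <<- beta2
  }
  fix("dep33", alpha = 7.377, beta1 = 0.688, beta2 = 1.349)
  fix("dep35", alpha = 2.457, beta1 = 0.119, beta2 = 0.828)
  fix("dis37", alpha = 3.483)
  fix("anx27", alpha = 5.527)
  fix("som16", alpha = 1.855)
  item_bank(dplyr::select(bank, -"number"))
}

#' Inject differential item functioning into one item
#'
#' Produces a reference/focal bank pair that differ only in one item. A
#' threshold shift (`group_shift`) yields uniform DIF; a slope ratio other
#' than 1 additionally yields non-uniform DIF (the focal discrimination is
#' `alpha * slope_ratio`).
#'
#' @param bank An [item_bank()].
#' @param item_id Item to perturb; must exist in the bank.
#' @param group_shift Amount added to both focal-group thresholds.
#' @param slope_ratio Multiplier on the focal-group discrimination (default 1).
#' @return A list with elements `reference` and `focal`, both item banks.
#' @examples
#' pair <- inject_dif(fixture_bank(), "dis41", group_shift = -0.5)
#' @export
inject_dif <- function(bank, item_id, group_shift, slope_ratio = 1) {
  bank <- item_bank(bank)
  i <- match(item_id, bank$item_id)
  if (is.na(i)) {
    abort(paste0("unknown item id: ", item_id))
  }
  focal <- bank
  focal$beta1[i] <- focal$beta1[i] + group_shift
  focal$beta2[i] <- focal$beta2[i] + group_shift
  focal$alpha[i] <- focal$alpha[i] * slope_ratio
  list(reference = bank, focal = item_bank(focal))
}

#' Read / write an item bank
#'
#' The delimited form is a comma-separated file with header
#' `item_id,scale,alpha,beta1,beta2`; the JSON mirror is an array of item
#' objects with the same fields. The format is chosen from the file
#' extension (`.json` vs anything else).
#'
#' @param path File path.
#' @param bank An [item_bank()] tibble.
#' @return `read_bank()` returns an [item_bank()]; `write_bank()` returns
#'   `path` invisibly.
#' @export
read_bank <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  item_bank(x)
}

#' @rdname read_bank
#' @export
write_bank <- function(bank, path) {
  bank <- item_bank(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(bank, path, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(bank, path)
  }
  invisible(path)
}
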