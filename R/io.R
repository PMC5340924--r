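#' Read / write response and covariate tables
#'
#' Responses are stored as delimited text with a header row: `person_id`
#' first, then one integer column per item. `read_responses()` validates
#' the layout (duplicate ids or columns, non-integer cells, ragged rows
#' are rejected with coordinates) and keeps missing cells as `NA` so that
#' [complete_cases()] can report exclusions.
#'
#' @param path File path.
#' @param responses Tibble with `person_id` plus item columns.
#' @param delim Field delimiter (default comma).
#' @return `read_responses()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
read_responses <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols(
                           person_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0("malformed response file; first problem at line ",
                 probs$row[1], ": ", probs$expected[1], " vs ",
                 probs$actual[1]))
  }
  if (!"person_id" %in% names(x)) {
    abort("response file must have a person_id column")
  }
  dup <- names(x)[duplicated(sub("\\.\\.\\.[0-9]+$", "", names(x)))]
  if (length(dup) > 0) {
    abort(paste0("duplicated item column(s): ",
                 paste(sub("\\.\\.\\.[0-9]+$", "", dup), collapse = ", ")))
  }
  if (anyDuplicated(x$person_id)) {
    abort(paste0("duplicated person_id: ",
                 paste(unique(x$person_id[duplicated(x$person_id)]),
                       collapse = ", ")))
  }
  items <- setdiff(names(x), "person_id")
  m <- as.matrix(x[items])
  frac <- which(!is.na(m) & m != floor(m), arr.ind = TRUE)
  if (nrow(frac) > 0) {
    abort(paste0("non-integer cell at person ", x$person_id[frac[1, 1]],
                 ", item ", items[frac[1, 2]]))
  }
  x[items] <- lapply(x[items], as.integer)
  inform(paste0("read ", nrow(x), " persons x ", length(items), " items (",
                sum(is.na(m)), " missing cells)"))
  x
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path, delim = ",") {
  readr::write_delim(responses, path, delim = delim)
  invisible(path)
}

#' @rdname read_responses
#' @export
read_covariates <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("person_id", "sex") %in% names(x))) {
    abort("covariate file must have person_id and sex columns")
  }
  x$person_id <- as.character(x$person_id)
  x
}
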