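REVIEW_COLUMNS <- c("review_id", "source", "drug", "text", "age",
                    "duration_months", "rating_year", "satisfaction_raw",
                    "satisfaction_scale")

#' Read and write review tables
#'
#' Reviews travel as CSV or JSONL (one JSON object per line) with the
#' documented column dictionary: `review_id`, `source`, `drug`, `text`,
#' `age`, `duration_months`, `rating_year`, `satisfaction_raw`,
#' `satisfaction_scale`. Banded columns (`age_band`, `duration_band`,
#' `satisfaction_5`) are accepted as-is when already present.
#'
#' @param path File path; format chosen by extension (`.csv` vs
#'   `.jsonl`/`.ndjson`).
#' @return A review tibble.
#' @export
read_reviews <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Review file not found: ", path), class = "emospect_input_error")
  }
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    df <- purrr::map_dfr(lines, function(l) {
      obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      obj <- lapply(obj, function(v) if (is.null(v)) NA else v)
      tibble::as_tibble(obj)
    })
  } else {
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                            encoding = "UTF-8"))
  }
  if (!all(c("review_id", "text") %in% names(df))) {
    abort("Review table must contain review_id and text columns.",
          class = "emospect_input_error")
  }
  df$review_id <- as.character(df$review_id)
  if ("drug" %in% names(df)) df$drug <- factor(df$drug, levels = DRUG_LEVELS)
  if ("source" %in% names(df)) df$source <- factor(df$source, levels = SOURCE_LEVELS)
  if ("age_band" %in% names(df)) df$age_band <- factor(df$age_band, levels = AGE_LEVELS)
  if ("duration_band" %in% names(df)) {
    df$duration_band <- factor(df$duration_band, levels = DURATION_LEVELS)
  }
  df
}

#' @rdname read_reviews
#' @param reviews A review tibble.
#' @export
write_reviews <- function(reviews, path) {
  out <- reviews[, setdiff(names(reviews), "clean"), drop = FALSE]
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, null = "null",
                       na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
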