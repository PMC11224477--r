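known_tillage <- c("CK", "SC", "SS", "DP", "NT", "SCR", "SSR", "DPR", "NTR")
known_varieties <- c("XY696", "XM6")

read_long_csv <- function(path, required, numeric_cols, strict,
                          dup_key = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE, name_repair = "minimal")
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("missing column(s) in ", path, ": ",
                        paste(missing_cols, collapse = ", ")))
  }
  df <- df[required]
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        rlang::abort(paste0("non-numeric `", col, "` at data row(s) ",
                            paste(utils::head(bad, 5), collapse = ", ")))
      }
      df[[col]] <- vn
    }
  }
  if (!is.null(dup_key)) {
    dup <- which(duplicated(df[dup_key]))
    if (length(dup)) {
      rlang::abort(paste0("duplicate ", paste(dup_key, collapse = "/"),
                          " at data row(s) ",
                          paste(utils::head(dup, 5), collapse = ", ")),
                   class = "grainfill_duplicate_rows")
    }
  }
  check_labels <- function(col, known) {
    unknown <- setdiff(unique(df[[col]]), known)
    if (length(unknown)) {
      msg <- paste0("unknown ", col, " label(s): ",
                    paste(unknown, collapse = ", "))
      if (strict) rlang::abort(msg) else rlang::warn(msg)
    }
  }
  if ("tillage" %in% names(df)) check_labels("tillage", known_tillage)
  if ("variety" %in% names(df)) check_labels("variety", known_varieties)
  tibble::as_tibble(df)
}

#' Read a long-format grain-filling CSV
#'
#' Expects a header with columns `year, tillage, variety, replicate,
#' dap, weight` (any order, any case). `dap` and `weight` must be
#' numeric and each unit's sampling dates unique; violations report the
#' offending rows. Unrecognized tillage or variety labels warn by
#' default (the schema is open to other designs) and error in strict
#' mode.
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, unknown treatment labels are an error.
#' @return A tibble of filling observations.
#' @export
read_filling_csv <- function(path, strict = FALSE) {
  read_long_csv(
    path,
    required = c("year", "tillage", "variety", "replicate", "dap", "weight"),
    numeric_cols = c("year", "dap", "weight"),
    strict = strict,
    dup_key = c("year", "tillage", "variety", "replicate", "dap")
  )
}

#' Read a long-format maturity-trait CSV
#'
#' Columns `year, tillage, variety, replicate, trait, value` (any
#' order, any case); one row per unit and trait.
#'
#' @inheritParams read_filling_csv
#' @return A tibble of trait records.
#' @export
read_trait_csv <- function(path, strict = FALSE) {
  read_long_csv(
    path,
    required = c("year", "tillage", "variety", "replicate", "trait", "value"),
    numeric_cols = c("year", "value"),
    strict = strict,
    dup_key = c("year", "tillage", "variety", "replicate", "trait")
  )
}

#' Write filling or trait tables to CSV
#'
#' Thin [readr::write_csv()] wrappers emitting the same schemas the
#' readers consume, so `read(write(x))` round-trips.
#'
#' @param data The tibble to write.
#' @param path Destination path.
#' @return `data`, invisibly.
#' @export
write_filling_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_filling_csv
#' @export
write_trait_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
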