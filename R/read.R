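#' Read a raw clinical cohort table
#'
#' Reads a patients-by-features table from CSV (header row) or JSON (array of
#' flat records). Column order is preserved. Cells matching a recognized
#' missing marker (empty string, `"NA"`, `"NaN"`, `"null"`, case-insensitive)
#' become `NA`; columns containing any other non-numeric value are kept as
#' character and later excluded by [curate()] with the reason logged.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param missing_markers Character vector of strings treated as missing.
#' @return A tibble with one row per patient, columns in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("age,bmi", "63,27.1", "55,NA", "71,31.4"), f)
#' read_cohort(f)
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        missing_markers = c("", "NA", "NaN", "null")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Input file does not exist: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = read_cohort_csv(path),
    json = read_cohort_json(path)
  )
  decode_cells(raw, missing_markers)
}

read_cohort_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) abort("CSV file has no header row.")
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  header <- trimws(split_csv(lines[1]))
  if (any(!nzchar(header))) abort("CSV header contains an empty feature name.")
  n_col <- length(header)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    # a trailing missing cell yields one fewer field from strsplit
    cells <- split_csv(paste0(lines[i], " "))
    cells[length(cells)] <- trimws(cells[length(cells)])
    if (length(cells) != n_col) {
      abort(sprintf(
        "Ragged CSV: row %d has %d cells under a %d-column header.",
        i - 1L, length(cells), n_col
      ))
    }
    trimws(cells)
  })
  m <- do.call(rbind, c(rows, list(matrix(character(), 0, n_col))))
  colnames(m) <- header
  as_tibble(as.data.frame(m, check.names = FALSE, stringsAsFactors = FALSE))
}

read_cohort_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) abort("JSON input must be an array of records.")
  if (length(recs) == 0L) abort("JSON input has no records.")
  features <- names(recs[[1]])
  if (is.null(features) || any(!nzchar(features))) {
    abort("JSON records must be flat objects with named fields.")
  }
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (!setequal(names(r), features) || length(r) != length(features)) {
      abort(sprintf("Ragged JSON: record %d does not match the first record's fields.", i))
    }
    vapply(features, function(f) {
      v <- r[[f]]
      if (is.null(v)) "" else as.character(v)
    }, character(1))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- features
  as_tibble(as.data.frame(m, check.names = FALSE, stringsAsFactors = FALSE))
}

# Turn recognized missing markers into NA and parse numeric columns; columns
# with unparseable cells stay character (flagged downstream).
decode_cells <- function(tbl, missing_markers) {
  markers <- tolower(missing_markers)
  out <- lapply(tbl, function(col) {
    if (is.numeric(col)) return(col)
    col <- as.character(col)
    col[tolower(trimws(col)) %in% markers] <- NA_character_
    parsed <- suppressWarnings(as.numeric(col))
    if (any(!is.na(col) & is.na(parsed))) col else parsed
  })
  as_tibble(out)
}
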