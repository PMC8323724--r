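#' Read a numeric CSV with missing-value tokens
#'
#' Reads an RFC-4180-style comma-separated file of real numbers into a numeric
#' matrix. Cells matching one of `missingTokens` (case-insensitive, after
#' trimming whitespace) become `NA`; every other cell must parse as a finite
#' real number.
#'
#' @param path path to a CSV file.
#' @param missingTokens character vector of tokens encoding a missing cell.
#'   The default accepts the empty field and the common `NA`/`NaN` spellings.
#' @param hasHeader logical; if `TRUE` the first row supplies column names.
#' @return a numeric matrix with row names `"1"..."N"` and the file's column
#'   names (or `V1...VM` without a header).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "1,2", "3,", "5,6"), f)
#' m <- readNumericCSV(f)
#' sum(is.na(m))  # 1
#' @export
readNumericCSV <- function(path, missingTokens = c("", "NA", "NaN", "nan"),
                           hasHeader = TRUE) {
  if (!file.exists(path)) .errIO(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    .errEmptyInput(sprintf("empty input file: %s", path))
  }
  # trailing blank lines are tolerated; interior blank lines are ragged rows
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  # strsplit drops a trailing empty field ("1," -> "1"); restore it
  nTrail <- vapply(lines, function(l) {
    if (endsWith(l, ",")) 1L else 0L
  }, integer(1L), USE.NAMES = FALSE)
  cells <- mapply(function(cl, nt) c(cl, rep("", nt)), cells, nTrail,
                  SIMPLIFY = FALSE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    .errShape(sprintf("ragged rows: widths %s", paste(unique(widths), collapse = ", ")))
  }
  M <- widths[1L]
  if (hasHeader) {
    header <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (length(cells) == 0L) .errEmptyInput("file holds a header but no data rows")
  } else {
    header <- paste0("V", seq_len(M))
  }
  N <- length(cells)
  tokens <- tolower(missingTokens)
  out <- matrix(NA_real_, N, M, dimnames = list(as.character(seq_len(N)), header))
  for (i in seq_len(N)) {
    row <- trimws(cells[[i]])
    isMiss <- tolower(row) %in% tokens
    vals <- suppressWarnings(as.numeric(row))
    bad <- which(!isMiss & (is.na(vals) | is.infinite(vals)))
    if (length(bad)) {
      .errParse(
        sprintf("cell '%s' at data row %d, column %d is not a finite number",
                row[bad[1L]], i, bad[1L]),
        row = i, col = bad[1L]
      )
    }
    vals[isMiss] <- NA_real_
    out[i, ] <- vals
  }
  out
}

#' Write a numeric matrix as CSV
#'
#' Missing cells are written as `missingToken`; numeric cells are written with
#' 17 significant digits so that [readNumericCSV()] round-trips the values
#' exactly.
#'
#' @param data numeric matrix (may contain `NA`).
#' @param path output file path.
#' @param missingToken string used for missing cells (default `"NaN"`).
#' @param header logical; write a header row of column names.
#' @return the path, invisibly.
#' @export
writeNumericCSV <- function(data, path, missingToken = "NaN", header = TRUE) {
  data <- .asDataset(data)
  dir <- dirname(path)
  if (!dir.exists(dir)) .errIO(sprintf("directory does not exist: %s", dir))
  fmt <- matrix(sprintf("%.17g", data), nrow(data), ncol(data))
  fmt[is.na(data)] <- missingToken
  rows <- apply(fmt, 1L, paste, collapse = ",")
  if (header) rows <- c(paste(colnames(data), collapse = ","), rows)
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .errIO(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Per-column missing-value profile
#'
#' @param data numeric matrix.
#' @return a list with `counts` (named integer vector, missing cells per
#'   column), `total` (MV, their sum) and `ratioPercent` (100 * MV / (N * M)).
#' @examples
#' m <- matrix(c(1, NA, 3, 4), 2, 2)
#' missingProfile(m)$ratioPercent  # 25
#' @export
missingProfile <- function(data) {
  data <- .asDataset(data)
  counts <- colSums(is.na(data))
  mv <- sum(counts)
  list(
    counts = counts,
    total = as.integer(mv),
    ratioPercent = 100 * mv / length(data)
  )
}
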