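#' Subject time-series container
#'
#' @param subject_id subject identifier.
#' @param data numeric `node x time` matrix without missing values.
#' @param tr_seconds repetition time in seconds.
#' @return object of class `subject_ts`.
#' @export
subject_ts <- function(subject_id, data, tr_seconds = 0.72) {
  data <- as.matrix(data)
  if (anyNA(data) || !is.numeric(data))
    stop("time series must be numeric with no missing values")
  if (nrow(data) < 2) stop("need at least 2 nodes")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr_seconds = tr_seconds), class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts %s: %d nodes x %d time points, TR = %gs>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Read a tab-delimited time-series matrix
#'
#' Files hold one time point per row and one node per column, no header.
#' Values are read at full double precision; a ragged or non-numeric file
#' raises an error naming the offending row/column.
#'
#' @param path file path.
#' @param subject_id identifier; defaults to the file name without
#'   extension.
#' @param tr_seconds repetition time in seconds.
#' @return a [subject_ts()] with a `node x time` data matrix.
#' @export
read_timeseries <- function(path, subject_id = NULL, tr_seconds = 0.72) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty time-series file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1)
    stop(sprintf("ragged TSV '%s': row %d has %d fields, expected %d",
                 path, which(lens != lens[1])[1], lens[lens != lens[1]][1],
                 lens[1]))
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(lens[1])))
  # vals is nodes x time if lens[1] > 1 (vapply transposes row-major input)
  bad <- which(is.na(vals) &
                 matrix(unlist(cells), nrow = lens[1]) != "NA")
  if (length(bad)) {
    col <- (bad[1] - 1) %% lens[1] + 1
    row <- (bad[1] - 1) %/% lens[1] + 1
    stop(sprintf("non-numeric cell in '%s' at row %d, column %d",
                 path, row, col))
  }
  mat <- if (is.matrix(vals)) vals else matrix(vals, nrow = 1)
  subject_ts(subject_id, mat, tr_seconds)
}

#' Write a numeric matrix as tab-delimited text
#'
#' Values are written with 17 significant digits so a write-then-read
#' round trip is bit exact.
#'
#' @param path file path.
#' @param mat numeric matrix (for time series: rows = time points).
#' @export
write_matrix <- function(path, mat) {
  mat <- as.matrix(mat)
  lines <- apply(mat, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort table
#'
#' Expects columns `subject_id,bmi,age,gender` plus optional `mean_fd` and
#' other metadata columns.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "bmi", "age", "gender")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id in cohort")
  tibble::as_tibble(tab)
}

#' Apply tabular cohort exclusion filters
#'
#' Removes subjects with missing BMI or demographics, excessive head motion
#' (mean frame-wise displacement above `fd_threshold`), and — when the
#' optional metadata columns `endocrine_disorder` / `recent_childbirth`
#' exist — subjects flagged there. Filters whose columns are absent are
#' recorded as not evaluable. The operation is idempotent.
#'
#' @param cohort cohort tibble (see [read_cohort()]).
#' @param fd_threshold mean frame-wise displacement cutoff (default 0.25).
#' @return list with `cohort` (retained rows) and `log` (tibble of
#'   `subject_id`, `reason` for each exclusion); the log carries a
#'   `not_evaluable` attribute naming filters that could not be applied.
#' @export
apply_exclusions <- function(cohort, fd_threshold = 0.25) {
  reasons <- character(0); ids <- character(0)
  drop <- rep(FALSE, nrow(cohort))
  mark <- function(which, reason) {
    new <- which & !drop
    ids <<- c(ids, cohort$subject_id[new])
    reasons <<- c(reasons, rep(reason, sum(new)))
    drop <<- drop | which
  }
  mark(is.na(cohort$bmi), "missing BMI")
  mark(is.na(cohort$age) | is.na(cohort$gender), "missing demographics")
  not_evaluable <- character(0)
  if ("mean_fd" %in% names(cohort)) {
    mark(!is.na(cohort$mean_fd) & cohort$mean_fd > fd_threshold,
         "head motion")
  } else not_evaluable <- c(not_evaluable, "head motion")
  for (col in c("endocrine_disorder", "recent_childbirth")) {
    if (col %in% names(cohort)) {
      mark(!is.na(cohort[[col]]) & cohort[[col]] %in% c(TRUE, 1, "yes"),
           gsub("_", " ", col))
    } else not_evaluable <- c(not_evaluable, gsub("_", " ", col))
  }
  kept <- cohort[!drop, , drop = FALSE]
  if (!nrow(kept)) warning("all subjects excluded")
  log <- tibble::tibble(subject_id = ids, reason = reasons)
  attr(log, "not_evaluable") <- not_evaluable
  list(cohort = kept, log = log)
}

#' Assign WHO-style BMI group labels
#'
#' Half-open intervals: underweight `(0, 18.5)`, healthy `[18.5, 25)`,
#' overweight `[25, 30)`, obese `[30, Inf)`.
#'
#' @param bmi numeric vector of positive BMI values.
#' @return factor with levels underweight, healthy, overweight, obese.
#' @export
assign_bmi_group <- function(bmi) {
  if (any(is.na(bmi)) || any(bmi <= 0)) stop("bmi must be positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "healthy", "overweight", "obese"))
}
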