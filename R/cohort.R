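# Worker-level cohort container and file I/O.

# numeric tolerance for score comparisons: VAS/PSS live on a 0.1 grid and
# 0.1 has no exact binary representation, so boundary tests like `vas >= 7.2`
# must not depend on the last ulp.
SCORE_TOL <- 1e-9

.cohort_fields <- c("id", "gender", "age", "education", "role", "sector",
                    "pss14", "vas")

.gender_levels <- c("male", "female")
.education_levels <- c("high_school_or_less", "bachelor", "master_or_more")
.role_levels <- c("unskilled", "skilled", "mid_level", "senior_executive")
.sector_levels <- c("manufacturing", "building", "commerce_service",
                    "agribusiness", "transport", "hospitality",
                    "health_social")

#' Construct a worker cohort
#'
#' A cohort is a data frame with one row per worker carrying demographics
#' (which may be missing) and the two stress scores `pss14` and `vas`, both on
#' the 0-10 scale at 0.1 resolution. Scores must be present and inside
#' \[0, 10\]; worker ids must be unique.
#'
#' @param data A data frame with columns `id`, `gender`, `age`, `education`,
#'   `role`, `sector`, `pss14`, `vas`. Missing demographic columns are added
#'   as `NA`; missing `pss14`/`vas` values are rejected.
#' @param provenance Free-text label recording where the records came from.
#' @return An object of class `cohort` (a data frame).
#' @export
cohort <- function(data, provenance = "unspecified") {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) {
    stop("empty cohort: at least one worker record is required", call. = FALSE)
  }
  for (f in c("pss14", "vas")) {
    if (!f %in% names(data)) {
      stop(sprintf("required score column '%s' is missing", f), call. = FALSE)
    }
  }
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  for (f in setdiff(.cohort_fields, names(data))) data[[f]] <- NA
  data <- data[.cohort_fields]

  data$pss14 <- validate_score(data$pss14, "pss14")
  data$vas <- validate_score(data$vas, "vas")
  if (anyDuplicated(data$id)) {
    stop("worker ids must be unique within a cohort", call. = FALSE)
  }
  if (!all(is.na(data$age))) {
    bad <- which(!is.na(data$age) & data$age < 16)
    if (length(bad)) {
      stop(sprintf("age below 16 years at row(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  structure(data,
            class = c("cohort", "data.frame"),
            provenance = provenance)
}

#' @rdname cohort
#' @param x Object to test or print.
#' @export
is_cohort <- function(x) inherits(x, "cohort")

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d workers (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Checks a score vector: numeric, no NA, inside [0,10]; values off the 0.1
# grid (beyond representation error) are kept but flagged once.
validate_score <- function(x, name) {
  if (!is.numeric(x)) {
    stop(sprintf("score column '%s' must be numeric", name), call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("score column '%s' has missing values at row(s) %s",
                 name, paste(utils::head(which(is.na(x)), 5L), collapse = ", ")),
         call. = FALSE)
  }
  out_of_range <- which(x < -SCORE_TOL | x > 10 + SCORE_TOL)
  if (length(out_of_range)) {
    stop(sprintf("score '%s' outside [0, 10] at row(s) %s",
                 name, paste(utils::head(out_of_range, 5L), collapse = ", ")),
         call. = FALSE)
  }
  off_grid <- abs(x * 10 - round(x * 10)) > 1e-6
  if (any(off_grid)) {
    warning(sprintf("%d value(s) in '%s' are not on the 0.1 measurement grid",
                    sum(off_grid), name), call. = FALSE)
  }
  pmin(pmax(as.numeric(x), 0), 10)
}

#' Read a worker cohort from a delimited file or spreadsheet
#'
#' Reads one worker record per data row. Column headers are matched to the
#' canonical fields through `column_map`; there is no header guessing, so
#' files with arbitrary export headers ("Perceived Stress Scale score", ...)
#' are handled by an explicit map.
#'
#' @param path Path to the input file.
#' @param dialect `"delimited"` (comma- or tab-separated, RFC-4180 quoting)
#'   or `"spreadsheet"` (XLSX, first sheet, first row = headers).
#' @param column_map Named character vector mapping canonical field names to
#'   file headers, e.g. `c(pss14 = "PSS total", vas = "VAS stress")`. Fields
#'   not named in the map are taken from identically-named columns when
#'   present, otherwise left missing. `pss14` and `vas` must resolve.
#' @param strict If `TRUE`, rows with missing scores are an error; otherwise
#'   they are dropped with a warning.
#' @return A [cohort].
#' @export
read_cohort <- function(path,
                        dialect = c("delimited", "spreadsheet"),
                        column_map = NULL,
                        strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)

  raw <- switch(dialect,
    delimited = {
      header <- readLines(path, n = 1L)
      sep <- if (grepl("\t", header)) "\t" else ","
      utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                        stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "", na.strings = c("NA", ""))
    },
    spreadsheet = as.data.frame(readxl::read_excel(path, sheet = 1L),
                                check.names = FALSE)
  )
  if (nrow(raw) == 0L) {
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  }

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in .cohort_fields) {
    src <- if (!is.null(column_map) && f %in% names(column_map)) {
      column_map[[f]]
    } else if (f %in% names(raw)) {
      f
    } else {
      NA_character_
    }
    if (!is.na(src) && !src %in% names(raw)) {
      stop(sprintf("mapped column '%s' (field '%s') not present in file",
                   src, f), call. = FALSE)
    }
    out[[f]] <- if (is.na(src)) NA else raw[[src]]
  }
  for (f in c("gender", "education", "role", "sector")) {
    out[[f]] <- as.character(out[[f]])
  }
  if (!all(is.na(out$age))) out$age <- as.numeric(out$age)
  for (f in c("pss14", "vas")) {
    if (all(is.na(out[[f]]))) {
      stop(sprintf("score column for '%s' not found; supply it in column_map",
                   f), call. = FALSE)
    }
    if (!is.numeric(out[[f]])) {
      suppressWarnings(num <- as.numeric(out[[f]]))
      if (anyNA(num) && !anyNA(out[[f]])) {
        stop(sprintf("score column for '%s' is not numeric", f), call. = FALSE)
      }
      out[[f]] <- num
    }
  }
  incomplete <- is.na(out$pss14) | is.na(out$vas)
  if (any(incomplete)) {
    msg <- sprintf("%d row(s) with missing pss14/vas scores", sum(incomplete))
    if (strict) stop(msg, call. = FALSE)
    warning(paste(msg, "dropped"), call. = FALSE)
    out <- out[!incomplete, , drop = FALSE]
    if (nrow(out) == 0L) stop("all rows had missing scores", call. = FALSE)
  }
  cohort(out, provenance = path)
}

#' Write a cohort to canonical delimited text
#'
#' Writes UTF-8 comma-separated text with the canonical headers; scores are
#' printed with exactly one decimal so that [read_cohort()] inverts the file
#' losslessly.
#'
#' @param x A [cohort].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(is_cohort(x))
  if (nrow(x) == 0L) stop("refusing to write an empty cohort", call. = FALSE)
  out <- as.data.frame(x)
  out$pss14 <- sprintf("%.1f", out$pss14)
  out$vas <- sprintf("%.1f", out$vas)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Summarize a cohort
#'
#' Descriptive summary used in participant tables: size, gender counts,
#' mean/SD of age and both scores (sample SD, n-1 denominator, computed over
#' non-missing values), and the prevalence of the reference-positive class
#' `pss14 >= pss_cutoff` (boundary inclusive).
#'
#' @param x A [cohort].
#' @param pss_cutoff Reference cut-off on the PSS14 scale (default 7.2).
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(x, pss_cutoff = 7.2) {
  stopifnot(is_cohort(x), nrow(x) >= 1L)
  mean_sd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(v), sd = stats::sd(v))
  }
  positive <- x$pss14 >= pss_cutoff - SCORE_TOL
  out <- list(
    n = nrow(x),
    n_male = sum(x$gender == "male", na.rm = TRUE),
    n_female = sum(x$gender == "female", na.rm = TRUE),
    n_missing_gender = sum(is.na(x$gender)),
    age_mean_sd = mean_sd(x$age),
    pss_mean_sd = mean_sd(x$pss14),
    vas_mean_sd = mean_sd(x$vas),
    pss_cutoff = pss_cutoff,
    n_positive = sum(positive),
    prevalence = mean(positive)
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d (%d men, %d women%s)\n", x$n, x$n_male, x$n_female,
              if (x$n_missing_gender)
                sprintf(", %d missing", x$n_missing_gender) else ""))
  cat(sprintf("age   %.0f +/- %.0f years\n",
              x$age_mean_sd[["mean"]], x$age_mean_sd[["sd"]]))
  cat(sprintf("pss14 %.1f +/- %.1f   vas %.1f +/- %.1f\n",
              x$pss_mean_sd[["mean"]], x$pss_mean_sd[["sd"]],
              x$vas_mean_sd[["mean"]], x$vas_mean_sd[["sd"]]))
  cat(sprintf("prevalence of pss14 >= %.1f: %d/%d (%.1f%%)\n",
              x$pss_cutoff, x$n_positive, x$n, 100 * x$prevalence))
  invisible(x)
}
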