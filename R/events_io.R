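#' Observation window
#'
#' Defines the span of calendar time covered by a dataset. All event times are
#' stored as fractional years; `t_max` is the last observation time, after
#' which every non-event is treated as right-censored.
#'
#' @param t_start Start of the observation window (fractional years).
#' @param t_max Last observation time (fractional years). The default,
#'   2010.999, denotes the end of year 2010.
#' @return An object of class `observation_window`.
#' @examples
#' observation_window(1990, 2010.999)
#' @export
observation_window <- function(t_start = 1900, t_max = 2010.999) {
  stopifnot(is.numeric(t_start), is.numeric(t_max),
            length(t_start) == 1L, length(t_max) == 1L,
            is.finite(t_start), is.finite(t_max))
  if (t_start >= t_max) {
    stop("t_start must be strictly less than t_max", call. = FALSE)
  }
  structure(list(t_start = t_start, t_max = t_max),
            class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> [%.3f, %.3f]\n", x$t_start, x$t_max))
  invisible(x)
}

#' Parse dates into fractional years
#'
#' Accepts bare years ("1998"), ISO-8601 dates ("1998-03-05") and decimal
#' years ("1998.25"). Bare years map to `year + 0.0`; full dates to
#' `year + (day_of_year - 1) / 365.25`; decimal years pass through.
#'
#' @param x Character vector of dates.
#' @return Numeric vector of fractional years. Unparseable entries raise an
#'   error listing their positions.
#' @examples
#' parse_fractional_year(c("1998", "2000-07-01", "2003.5"))
#' @export
parse_fractional_year <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))

  is_year <- grepl("^[0-9]{4}$", x)
  out[is_year] <- as.numeric(x[is_year])

  is_dec <- !is_year & grepl("^[0-9]{4}\\.[0-9]+$", x)
  out[is_dec] <- as.numeric(x[is_dec])

  is_iso <- !is_year & !is_dec & grepl("^[0-9]{4}-[0-9]{2}(-[0-9]{2})?$", x)
  if (any(is_iso)) {
    iso <- x[is_iso]
    iso[nchar(iso) == 7L] <- paste0(iso[nchar(iso) == 7L], "-01")
    d <- as.Date(iso, format = "%Y-%m-%d")
    yr <- as.numeric(format(d, "%Y"))
    yday <- as.numeric(format(d, "%j"))
    val <- yr + (yday - 1) / 365.25
    val[is.na(d)] <- NA_real_
    out[is_iso] <- val
  }

  bad <- which(is.na(out) | !is.finite(out))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable date(s) at position(s): %s (e.g. '%s')",
                 paste(utils::head(bad, 10L), collapse = ", "), x[bad[1L]]),
         call. = FALSE)
  }
  out
}

## canonical semicolon-joined disease annotation: sorted, unique, no blanks
canonical_diseases <- function(x) {
  vapply(strsplit(as.character(x), ";", fixed = TRUE), function(d) {
    d <- sort(unique(trimws(d)))
    paste(d[nzchar(d)], collapse = ";")
  }, character(1L))
}

split_diseases <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(d) {
    d <- trimws(d)
    d[nzchar(d)]
  })
}

#' Construct a study table
#'
#' A study table holds one row per (drug, study) event: the drug token, an
#' opaque study identifier, the event time in fractional years and the set of
#' diseases annotated on the study (semicolon-separated, possibly empty).
#' Rows are kept in canonical order (time, then drug_id, then study_id) so
#' that all downstream outputs are bit-reproducible.
#'
#' @param drug_id,study_id Character vectors of tokens.
#' @param time Numeric vector of fractional years.
#' @param diseases Character vector of semicolon-separated disease tokens
#'   (may be empty strings), or a list of character vectors.
#' @param window An [observation_window()].
#' @return A data.frame of class `study_table` with attribute `window`.
#' @export
study_table <- function(drug_id, study_id, time, diseases = "",
                        window = observation_window()) {
  drug_id <- as.character(drug_id)
  study_id <- as.character(study_id)
  time <- as.numeric(time)
  if (is.list(diseases)) {
    diseases <- vapply(diseases, function(d) paste(d, collapse = ";"),
                       character(1L))
  }
  diseases <- as.character(diseases)
  n <- max(length(drug_id), length(study_id), length(time))
  for (len in c(length(drug_id), length(study_id), length(time),
                length(diseases))) {
    stopifnot(len == 1L || len == n || (len == 0L && n == 0L))
  }
  drug_id <- rep_len(drug_id, n)
  study_id <- rep_len(study_id, n)
  time <- rep_len(time, n)
  diseases <- rep_len(diseases, n)
  if (any(!nzchar(drug_id)) || any(!nzchar(study_id))) {
    stop("drug_id and study_id must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(time))) stop("study times must be finite", call. = FALSE)
  if (anyDuplicated(paste(drug_id, study_id, sep = "\r"))) {
    stop("duplicate (drug_id, study_id) pairs", call. = FALSE)
  }
  df <- data.frame(drug_id = drug_id, study_id = study_id, time = time,
                   diseases = canonical_diseases(diseases),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time, df$drug_id, df$study_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, window = window, class = c("study_table", "data.frame"))
}

#' Construct an adoption table
#'
#' One row per (drug, disease) adoption: the first time the disease was
#' paired with the drug. Rows are canonically ordered by (time, drug_id,
#' disease_id).
#'
#' @param drug_id,disease_id Character vectors of tokens.
#' @param time Numeric vector of adoption times (fractional years).
#' @param window An [observation_window()].
#' @return A data.frame of class `adoption_table`.
#' @export
adoption_table <- function(drug_id, disease_id, time,
                           window = observation_window()) {
  drug_id <- as.character(drug_id)
  disease_id <- as.character(disease_id)
  time <- as.numeric(time)
  n <- max(length(drug_id), length(disease_id), length(time))
  for (len in c(length(drug_id), length(disease_id), length(time))) {
    stopifnot(len == 1L || len == n || (len == 0L && n == 0L))
  }
  drug_id <- rep_len(drug_id, n)
  disease_id <- rep_len(disease_id, n)
  time <- rep_len(time, n)
  if (anyDuplicated(paste(drug_id, disease_id, sep = "\r"))) {
    stop("duplicate (drug_id, disease_id) pairs", call. = FALSE)
  }
  if (any(!is.finite(time))) {
    stop("adoption times must be finite", call. = FALSE)
  }
  df <- data.frame(drug_id = drug_id, disease_id = disease_id, time = time,
                   stringsAsFactors = FALSE)
  df <- df[order(df$time, df$drug_id, df$disease_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, window = window, class = c("adoption_table", "data.frame"))
}

#' Read a study table from TSV
#'
#' The file must be tab-separated with a header naming at least `drug_id`,
#' `study_id`, `date` and `diseases`. Dates may be bare years, ISO-8601 dates
#' or decimal years (see [parse_fractional_year()]). Rows outside the
#' observation window are dropped (a message reports how many); duplicated
#' (drug, study) pairs are collapsed to the earliest date.
#'
#' @param path Path to a TSV file.
#' @param window An [observation_window()]; rows outside it are dropped.
#' @return A `study_table`.
#' @export
read_study_table <- function(path, window = observation_window()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  required <- c("drug_id", "study_id", "date", "diseases")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  time <- tryCatch(parse_fractional_year(raw$date), error = function(e) {
    ## re-anchor positions to file line numbers (header is line 1)
    stop(sprintf("date parse failure in %s: %s (positions are data rows; add 1 for file lines)",
                 path, conditionMessage(e)), call. = FALSE)
  })

  inside <- time >= window$t_start & time <= window$t_max
  if (any(!inside)) {
    message(sprintf("read_study_table: dropped %d row(s) outside [%.3f, %.3f]",
                    sum(!inside), window$t_start, window$t_max))
  }
  raw <- raw[inside, , drop = FALSE]
  time <- time[inside]

  ## collapse duplicated (drug, study) pairs to the earliest date
  key <- paste(raw$drug_id, raw$study_id, sep = "\r")
  ord <- order(time, raw$drug_id, raw$study_id)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)

  study_table(drug_id = raw$drug_id[keep], study_id = raw$study_id[keep],
              time = time[keep], diseases = raw$diseases[keep],
              window = window)
}

#' Write a study table to TSV
#'
#' Dates are written as decimal years so that `read_study_table()` recovers
#' the table exactly.
#'
#' @param x A `study_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_study_table <- function(x, path) {
  stopifnot(inherits(x, "study_table"))
  out <- data.frame(drug_id = x$drug_id, study_id = x$study_id,
                    date = format_fractional_year(x$time),
                    diseases = x$diseases, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read an adoption table from TSV
#'
#' Expects header columns `drug_id`, `disease_id`, `year`.
#'
#' @param path Path to a TSV file.
#' @param window An [observation_window()].
#' @return An `adoption_table`.
#' @export
read_adoption_table <- function(path, window = observation_window()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  required <- c("drug_id", "disease_id", "year")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  adoption_table(raw$drug_id, raw$disease_id,
                 parse_fractional_year(raw$year), window = window)
}

#' Write an adoption table to TSV
#'
#' @param x An `adoption_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_adoption_table <- function(x, path) {
  stopifnot(inherits(x, "adoption_table"))
  out <- data.frame(drug_id = x$drug_id, disease_id = x$disease_id,
                    year = format_fractional_year(x$time),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

format_fractional_year <- function(t) {
  ## integral years print bare ("1998"), fractional ones with full precision
  ifelse(t == floor(t), sprintf("%d", as.integer(t)),
         sub("0+$", "", sprintf("%.10f", t)))
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' Derive adoption events from a study table
#'
#' A disease adopts a drug the first time the two are paired in a study; the
#' adoption time is the minimum study time over all studies mentioning both.
#' Studies with no annotated diseases contribute no adoptions.
#'
#' @param events A `study_table`.
#' @return An `adoption_table` (empty if no study carries a disease).
#' @export
derive_adoptions <- function(events) {
  stopifnot(inherits(events, "study_table"))
  window <- attr(events, "window")
  dis <- split_diseases(events$diseases)
  n_per <- lengths(dis)
  if (nrow(events) == 0L || sum(n_per) == 0L) {
    return(adoption_table(character(0), character(0), numeric(0),
                          window = window))
  }
  long_drug <- rep(events$drug_id, n_per)
  long_time <- rep(events$time, n_per)
  long_dis <- unlist(dis, use.names = FALSE)
  key <- paste(long_drug, long_dis, sep = "\r")
  first_time <- tapply(long_time, key, min)
  keys <- strsplit(names(first_time), "\r", fixed = TRUE)
  adoption_table(drug_id = vapply(keys, `[[`, character(1L), 1L),
                 disease_id = vapply(keys, `[[`, character(1L), 2L),
                 time = as.numeric(first_time), window = window)
}

#' Birth times of drugs
#'
#' A drug's birth is its first appearance in the dataset: the minimum study
#' time over all its studies (or the minimum adoption time when given an
#' adoption table).
#'
#' @param events A `study_table` or `adoption_table`.
#' @return A named numeric vector (names are drug ids, sorted), in
#'   fractional years.
#' @export
birth_times <- function(events) {
  stopifnot(inherits(events, "study_table") ||
              inherits(events, "adoption_table"))
  if (nrow(events) == 0L) return(stats::setNames(numeric(0), character(0)))
  b <- tapply(events$time, events$drug_id, min)
  out <- as.numeric(b)
  names(out) <- names(b)
  out[order(names(out))]
}
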