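#' Read a payroll shift log
#'
#' Reads a delimited text file of realized work shifts (one row per shift)
#' into a validated, canonically ordered data frame. Timestamps are naive
#' local clock times at minute precision; durations are literal clock
#' differences. Exact duplicate rows are dropped (counted), and rows whose
#' end does not lie strictly after their start are rejected (counted).
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Named list mapping the roles `id`, `start`, `end` to
#'   column names in the file, plus the field `sep` (default comma).
#' @return A `data.frame` with columns `employee_id` (character), `start`,
#'   `end` (`POSIXct`, UTC-naive), sorted by `(employee_id, start)`, with
#'   attributes `dropped_duplicates` and `dropped_nonpositive`.
#' @export
read_shift_log <- function(path,
                           dialect = list(id = "employee_id",
                                          start = "start", end = "end",
                                          sep = ",")) {
  sep <- dialect$sep %||% ","
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE)
  need <- c(dialect$id %||% "employee_id",
            dialect$start %||% "start",
            dialect$end %||% "end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stopf("shift log %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  start <- parse_timestamp(raw[[need[2]]])
  end <- parse_timestamp(raw[[need[3]]])
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stopf("unparseable timestamp in %s at line(s) %s (1 = first data row)",
          path, paste(utils::head(bad, 5), collapse = ", "))
  }
  rec <- data.frame(employee_id = raw[[need[1]]], start = start, end = end,
                    stringsAsFactors = FALSE)
  dup <- duplicated(rec)
  rec <- rec[!dup, , drop = FALSE]
  nonpos <- rec$end <= rec$start
  rec <- rec[!nonpos, , drop = FALSE]
  if (any(dup)) message(sum(dup), " exact duplicate row(s) dropped")
  if (any(nonpos)) {
    message(sum(nonpos), " row(s) with end <= start rejected")
  }
  rec <- rec[order(rec$employee_id, rec$start, rec$end), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "dropped_duplicates") <- sum(dup)
  attr(rec, "dropped_nonpositive") <- sum(nonpos)
  rec
}

#' Write a shift log
#'
#' Inverse of [read_shift_log()]: serializes shift records as UTF-8 CSV with
#' ISO-8601 timestamps.
#'
#' @param records Data frame with columns `employee_id`, `start`, `end`.
#' @param path Output file path.
#' @export
write_shift_log <- function(records, path) {
  out <- data.frame(employee_id = records$employee_id,
                    start = format_timestamp(records$start),
                    end = format_timestamp(records$end))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sickness-absence log
#'
#' Reads dated sickness-absence (SA) indicators, one row per employee-day.
#' Duplicate employee-days collapse to one record; output is sorted.
#'
#' @param path Path to a CSV with columns `employee_id` and `date`
#'   (ISO-8601 calendar dates).
#' @return A `data.frame` with columns `employee_id` (character) and `date`
#'   (`Date`), deduplicated and sorted.
#' @export
read_sa_log <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("employee_id", "date") %in% names(raw))) {
    stopf("SA log %s must have columns employee_id, date", path)
  }
  if (nrow(raw) == 0) {
    return(data.frame(employee_id = character(0),
                      date = as.Date(character(0))))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad)) {
    stopf("unparseable date in %s at line(s) %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  }
  rec <- data.frame(employee_id = raw$employee_id, date = date,
                    stringsAsFactors = FALSE)
  rec <- unique(rec)
  rec <- rec[order(rec$employee_id, rec$date), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write a sickness-absence log
#'
#' @param records Data frame with columns `employee_id`, `date`.
#' @param path Output file path.
#' @export
write_sa_log <- function(records, path) {
  out <- data.frame(employee_id = records$employee_id,
                    date = format(records$date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CODEBOOK_STORE_VERSION <- 1L

#' Construct a codebook store
#'
#' A codebook store is the released reference object of a clustering run:
#' the embedding parameters, every employee's three per-dimension
#' permutation-distribution codebooks, and the cluster labels. New series
#' are assigned to clusters against it with [assign_to_clusters()].
#'
#' @param m Embedding dimension (integer, >= 2).
#' @param t Embedding delay (integer, >= 1).
#' @param entries Named list: employee id -> named list of three
#'   [codebook] objects (`shift_length`, `rest_after`, `start_hour`).
#' @param labels Named integer vector of cluster labels, one per employee
#'   in `entries`.
#' @return An object of class `codebook_store`.
#' @export
codebook_store <- function(m, t, entries, labels) {
  store <- structure(
    list(m = as.integer(m), t = as.integer(t),
         entries = entries, labels = labels),
    class = "codebook_store"
  )
  validate_codebook_store(store)
  store
}

validate_codebook_store <- function(store) {
  if (store$m < 2L || store$t < 1L) stopf("need m >= 2 and t >= 1")
  ids <- names(store$entries)
  if (length(ids) && !setequal(ids, names(store$labels))) {
    stopf("codebook store labels must cover exactly the stored employees")
  }
  for (id in ids) {
    cbs <- store$entries[[id]]
    if (!all(ws_dims() %in% names(cbs))) {
      stopf("employee %s lacks a codebook for some dimension", id)
    }
    for (d in ws_dims()) {
      p <- codebook_frequencies(cbs[[d]])
      if (length(p) && abs(sum(p) - 1) > 1e-9) {
        stopf("frequencies of %s/%s do not sum to 1", id, d)
      }
    }
  }
  invisible(store)
}

#' Write a codebook store to JSON
#'
#' Serializes a [codebook_store()] as versioned JSON. Codeword keys are
#' comma-joined 0-based ranks (e.g. `"0,2,1"`); counts, totals and full
#' precision frequencies are stored so that a read after a write
#' reconstructs the store exactly.
#'
#' @param store A `codebook_store`.
#' @param path Output file path.
#' @export
write_codebook_store <- function(store, path) {
  validate_codebook_store(store)
  ser_cb <- function(cb) {
    list(total = cb$total,
         counts = as.list(cb$counts),
         frequencies = as.list(codebook_frequencies(cb)))
  }
  payload <- list(
    format = "shiftpdc-codebook-store",
    version = CODEBOOK_STORE_VERSION,
    m = store$m, t = store$t,
    labels = as.list(store$labels),
    entries = lapply(store$entries, function(cbs) lapply(cbs, ser_cb))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a codebook store from JSON
#'
#' @param path Path to a file written by [write_codebook_store()].
#' @return A `codebook_store`.
#' @export
read_codebook_store <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(payload$format, "shiftpdc-codebook-store")) {
    stopf("%s is not a codebook store file", path)
  }
  if (!identical(as.integer(payload$version), CODEBOOK_STORE_VERSION)) {
    stopf("codebook store version %s not supported (expected %d)",
          payload$version %||% "<missing>", CODEBOOK_STORE_VERSION)
  }
  m <- as.integer(payload$m)
  t <- as.integer(payload$t)
  de_cb <- function(x) {
    counts <- unlist(x$counts)
    if (is.null(counts)) counts <- numeric(0)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    new_codebook(counts[order(names(counts))], total = as.numeric(x$total),
                 m = m, t = t)
  }
  entries <- lapply(payload$entries, function(cbs) lapply(cbs, de_cb))
  labels <- unlist(payload$labels)
  if (is.null(labels)) labels <- stats::setNames(integer(0), character(0))
  storage.mode(labels) <- "integer"
  codebook_store(m, t, entries, labels[names(entries)])
}
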