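#' Build a focal-record table
#'
#' One row per 5-minute focal sample: `date`, `focal_id`, and three
#' semicolon-joined id sets — `within10m` (party co-residence),
#' `within1m` (direct association) and `grooming` (partners in any bout,
#' giving or receiving). Invariants enforced: the focal never appears in
#' its own associate sets, `within1m` is nested in `within10m`, `grooming`
#' is nested in `within1m`, and all ids resolve against the roster.
#'
#' @param date vector coercible to `Date`.
#' @param focal_id character vector of focal ids.
#' @param within10m,within1m,grooming lists of character vectors (or
#'   semicolon-joined strings) of associate ids.
#' @param roster a `roster` used for referential validation.
#' @param study_window optional length-2 `Date` vector; records outside it
#'   are excluded with a logged warning.
#' @return a `focal_records` data frame with list-free (semicolon-joined)
#'   associate fields.
#' @export
focal_records <- function(date, focal_id, within10m, within1m, grooming,
                          roster, study_window = NULL) {
  date <- as.Date(date)
  focal_id <- as.character(focal_id)
  as_sets <- function(x) if (is.list(x)) x else split_ids(as.character(x))
  w10 <- as_sets(within10m); w1 <- as_sets(within1m); gr <- as_sets(grooming)
  stopifnot(length(date) == length(focal_id),
            length(w10) == length(focal_id),
            length(w1) == length(focal_id),
            length(gr) == length(focal_id))
  logs <- character()

  known <- roster$id
  all_ids <- unique(c(unlist(w10), unlist(w1), unlist(gr), focal_id))
  unknown <- setdiff(all_ids, known)
  if (length(unknown)) {
    stop_dyadnet("focal", "id(s) not in roster: %s",
                 paste(unknown, collapse = ", "))
  }
  self_assoc <- vapply(seq_along(focal_id), function(i) {
    focal_id[i] %in% c(w10[[i]], w1[[i]], gr[[i]])
  }, logical(1))
  if (any(self_assoc)) {
    stop_dyadnet("focal", "focal listed in its own associate set at row(s): %s",
                 paste(which(self_assoc), collapse = ", "))
  }
  # closeness implies co-residence: promote 1 m ids missing from 10 m
  n_promoted <- 0L
  for (i in seq_along(focal_id)) {
    extra <- setdiff(w1[[i]], w10[[i]])
    if (length(extra)) {
      w10[[i]] <- c(w10[[i]], extra)
      n_promoted <- n_promoted + length(extra)
    }
    extra_g <- setdiff(gr[[i]], w1[[i]])
    if (length(extra_g)) {
      w1[[i]] <- c(w1[[i]], extra_g)
      w10[[i]] <- unique(c(w10[[i]], extra_g))
      n_promoted <- n_promoted + length(extra_g)
    }
  }
  if (n_promoted > 0) {
    logs <- c(logs, log_line("WARN", "focal", sprintf(
      "%d close-range id(s) promoted into enclosing proximity sets", n_promoted)))
  }
  keep <- rep(TRUE, length(date))
  if (!is.null(study_window)) {
    sw <- as.Date(study_window)
    keep <- date >= sw[1] & date <= sw[2]
    if (any(!keep)) {
      logs <- c(logs, log_line("WARN", "focal", sprintf(
        "%d record(s) outside study window excluded", sum(!keep))))
      warn_dyadnet("focal", "%d record(s) outside study window excluded",
                   sum(!keep))
    }
  }
  d <- data.frame(date = date, focal_id = focal_id,
                  within10m = join_ids(w10), within1m = join_ids(w1),
                  grooming = join_ids(gr), stringsAsFactors = FALSE)
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("focal_records", "data.frame")
  append_log(d, logs)
}

#' Read focal records from delimited text
#'
#' Expects columns `date`, `focal_id`, `within10m`, `within1m`,
#' `grooming`; associate sets are semicolon-joined id lists within a
#' field. All records are validated against the roster (unknown ids and
#' self-association are hard errors).
#'
#' @inheritParams focal_records
#' @param path input file path.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @return a `focal_records` data frame.
#' @export
load_focal_records <- function(path, roster, study_window = NULL, sep = ",") {
  if (!file.exists(path)) stop_dyadnet("focal", "file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("date", "focal_id", "within10m", "within1m", "grooming")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_dyadnet("focal", "missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  focal_records(d$date, d$focal_id, d$within10m, d$within1m, d$grooming,
                roster = roster, study_window = study_window)
}

#' Write focal records as delimited text
#'
#' @param records a `focal_records` table.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_focal_records <- function(records, path, sep = ",") {
  out <- as.data.frame(records)
  out$date <- as.character(out$date)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-individual focal sampling effort
#'
#' @param records a `focal_records` table.
#' @return list with `n_records`, `per_individual` (named count vector),
#'   `mean_per_individual` and `sd_per_individual`.
#' @export
focal_summary <- function(records) {
  counts <- table(records$focal_id)
  list(
    n_records = nrow(records),
    per_individual = c(counts),
    mean_per_individual = mean(counts),
    sd_per_individual = stats::sd(counts)
  )
}

#' @export
print.focal_records <- function(x, ...) {
  cat(sprintf("<focal_records> %d samples, %d focal individual(s), %s to %s\n",
              nrow(x), length(unique(x$focal_id)),
              min(x$date), max(x$date)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
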