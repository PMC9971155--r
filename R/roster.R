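#' Build a roster of study subjects
#'
#' A roster is a data frame with one row per individual: `id`, `sex`
#' (`"F"`/`"M"`), `age_years` (decimal years at the study midpoint),
#' `group_id`, `maternal_line` and a logical `excluded` flag. The
#' `maternal_line` field carries the id of the individual's mother (or a
#' matriline founder label when the mother is unknown or outside the
#' study); two individuals are maternal kin when they share a
#' `maternal_line` (maternal siblings) or one's `maternal_line` equals the
#' other's `id` (mother-offspring). Individuals younger than `min_age`
#' years are flagged `excluded` rather than dropped, mirroring the field
#' convention that infants travel with their mothers and are not scored as
#' independent subjects.
#'
#' @param id character vector of unique short identifiers.
#' @param sex character vector, each element `"F"` or `"M"`.
#' @param age_years non-negative decimal ages in years.
#' @param group_id group label(s), recycled if length 1.
#' @param maternal_line maternal-line labels (mother id or founder label).
#' @param min_age minimum subject age in years (default 4); younger
#'   individuals are flagged `excluded`.
#' @return a `roster` data frame.
#' @export
roster <- function(id, sex, age_years, group_id, maternal_line,
                   min_age = 4) {
  id <- as.character(id)
  sex <- as.character(sex)
  if (length(group_id) == 1L) group_id <- rep(group_id, length(id))
  maternal_line <- as.character(maternal_line)
  validate_roster_fields(id, sex, age_years)
  r <- data.frame(
    id = id, sex = sex, age_years = as.numeric(age_years),
    group_id = as.character(group_id), maternal_line = maternal_line,
    excluded = as.numeric(age_years) < min_age,
    stringsAsFactors = FALSE
  )
  class(r) <- c("roster", "data.frame")
  attr(r, "min_age") <- min_age
  r
}

validate_roster_fields <- function(id, sex, age_years) {
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop_dyadnet("roster", "duplicate id(s): %s", paste(dup, collapse = ", "))
  }
  bad_sex <- unique(sex[!sex %in% c("F", "M")])
  if (length(bad_sex)) {
    stop_dyadnet("roster", "unknown sex code(s): %s",
                 paste(bad_sex, collapse = ", "))
  }
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop_dyadnet("roster", "age_years must be non-negative and non-missing")
  }
  invisible(TRUE)
}

#' Read a roster from delimited text
#'
#' Expects columns `id`, `sex`, `group`, `maternal_line` and either `age`
#' (decimal years) or `birthdate` (ISO date, converted to age at
#' `study_midpoint`). Ages given as "years and months" should be encoded
#' as decimal years (months/12) before loading.
#'
#' @param path file path to a comma- (default) or tab-delimited table with
#'   a header row.
#' @param group_filter optional group id; when given, only that group's
#'   rows are kept.
#' @param min_age minimum subject age in years (default 4).
#' @param study_midpoint date used to convert `birthdate` to age when the
#'   file has no `age` column.
#' @param sep field separator (`","` or `"\t"`).
#' @return a `roster` data frame; exclusions are recorded in [run_log()].
#' @export
load_roster <- function(path, group_filter = NULL, min_age = 4,
                        study_midpoint = NULL, sep = ",") {
  if (!file.exists(path)) stop_dyadnet("roster", "file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "sex", "group", "maternal_line")
  missing_cols <- setdiff(need, names(d))
  has_age <- "age" %in% names(d)
  has_bd <- "birthdate" %in% names(d)
  if (!has_age && !has_bd) missing_cols <- c(missing_cols, "age|birthdate")
  if (length(missing_cols)) {
    stop_dyadnet("roster", "missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  logs <- character()
  if (!is.null(group_filter)) {
    d <- d[d$group %in% group_filter, , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    warn_dyadnet("roster", "roster is empty after filtering")
    r <- roster(character(), character(), numeric(), character(),
                character(), min_age = min_age)
    return(append_log(r, log_line("WARN", "roster", "empty roster loaded")))
  }
  if (has_age) {
    age <- as.numeric(d$age)
  } else {
    if (is.null(study_midpoint)) {
      stop_dyadnet("roster", "birthdate column requires study_midpoint")
    }
    age <- as.numeric(as.Date(study_midpoint) - as.Date(d$birthdate)) / 365.25
  }
  r <- roster(d$id, d$sex, age, d$group, d$maternal_line, min_age = min_age)
  n_exc <- sum(r$excluded)
  if (n_exc > 0) {
    logs <- c(logs, log_line("WARN", "roster", sprintf(
      "%d individual(s) under min_age %.3g flagged excluded: %s",
      n_exc, min_age, paste(r$id[r$excluded], collapse = ", "))))
  }
  append_log(r, logs)
}

#' Write a roster as delimited text
#'
#' @param r a `roster`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_roster <- function(r, path, sep = ",") {
  out <- data.frame(id = r$id, sex = r$sex, age = r$age_years,
                    group = r$group_id, maternal_line = r$maternal_line,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Active (non-excluded) subjects of one group
#'
#' @param r a `roster`.
#' @param group_id optional group id filter.
#' @return the roster rows that are not flagged excluded.
#' @export
active_roster <- function(r, group_id = NULL) {
  keep <- !r$excluded
  if (!is.null(group_id)) keep <- keep & r$group_id %in% group_id
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.roster <- function(x, ...) {
  cat(sprintf("<roster> %d individuals (%d excluded) in %d group(s)\n",
              nrow(x), sum(x$excluded), length(unique(x$group_id))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# TRUE where individuals i and j are maternal kin (mother-offspring or
# maternal siblings) under the maternal_line encoding.
maternal_kin <- function(id_a, id_b, roster) {
  ml <- stats::setNames(roster$maternal_line, roster$id)
  same_line <- ml[id_a] == ml[id_b]
  mother_of <- ml[id_a] == id_b | ml[id_b] == id_a
  unname(same_line | mother_of)
}
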