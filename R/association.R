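#' Daily 1/0 binarization of a focal-record stream
#'
#' Collapses focal samples to the sampling-period ("date", i.e. 24 h)
#' level: a dyad scores an event on a day if its members were observed
#' associating at least once that day on the chosen stream, from either
#' member's focal samples. An individual counts as "identified" on a day
#' if it was focal at least once or appeared in any focal's 10 m set;
#' identification is measure-independent so the three streams share their
#' simple-ratio denominators (`identified_rule = "focal_only"` restricts
#' identification to focal individuals instead).
#'
#' @param records a `focal_records` table (one group).
#' @param roster a `roster` restricted to the same group, excluded
#'   individuals removed.
#' @param measure `"party10m"`, `"direct1m"` or `"grooming"`; `"all"`
#'   (default) keeps all three event streams.
#' @param identified_rule `"inclusive"` (default) or `"focal_only"`.
#' @return a `daily_stream`: list with `ids` (canonical order), `days`,
#'   `identified` (day-by-individual logical matrix), `dyads` (the group's
#'   `dyad_table`), `pa`/`pb` (member column positions per dyad) and
#'   `events` (per measure, a list over days of integer dyad indices).
#' @export
binarize_daily <- function(records, roster, measure = "all",
                           identified_rule = c("inclusive", "focal_only")) {
  identified_rule <- match.arg(identified_rule)
  if (nrow(records) == 0L) {
    stop_dyadnet("association", "empty record sequence")
  }
  r <- roster[order(roster$id), , drop = FALSE]
  ids <- r$id
  recs <- records[records$focal_id %in% ids, , drop = FALSE]
  if (nrow(recs) == 0L) {
    stop_dyadnet("association", "no records for group %s", r$group_id[1])
  }
  dyads <- enumerate_dyads(r)
  n <- length(ids)
  kidx <- matrix(0L, n, n, dimnames = list(ids, ids))
  cmb <- utils::combn(n, 2L)
  kidx[cbind(cmb[1, ], cmb[2, ])] <- seq_len(ncol(cmb))
  kidx[cbind(cmb[2, ], cmb[1, ])] <- seq_len(ncol(cmb))

  days <- sort(unique(recs$date))
  day_of <- match(recs$date, days)
  measures <- c("party10m", "direct1m", "grooming")
  want <- if (measure == "all") measures else match.arg(measure, measures)

  identified <- matrix(FALSE, length(days), n,
                       dimnames = list(as.character(days), ids))
  events <- stats::setNames(
    rep(list(vector("list", length(days))), length(measures)), measures)

  w10 <- split_ids(recs$within10m)
  w1 <- split_ids(recs$within1m)
  gr <- split_ids(recs$grooming)
  sets <- list(party10m = w10, direct1m = w1, grooming = gr)

  for (d in seq_along(days)) {
    rows <- which(day_of == d)
    focals <- recs$focal_id[rows]
    seen <- focals
    if (identified_rule == "inclusive") {
      seen <- c(seen, unlist(w10[rows], use.names = FALSE))
    }
    identified[d, match(unique(seen), ids)] <- TRUE
    for (m in measures) {
      ss <- sets[[m]][rows]
      len <- lengths(ss)
      if (sum(len) == 0L) {
        events[[m]][[d]] <- integer()
      } else {
        a <- rep(focals, len)
        b <- unlist(ss, use.names = FALSE)
        events[[m]][[d]] <- sort(unique(kidx[cbind(match(a, ids),
                                                   match(b, ids))]))
      }
    }
  }
  out <- list(ids = ids, days = days, identified = identified,
              dyads = dyads, pa = match(dyads$member_a, ids),
              pb = match(dyads$member_b, ids),
              events = if (measure == "all") events else events[want],
              identified_rule = identified_rule)
  class(out) <- "daily_stream"
  out
}

#' @export
print.daily_stream <- function(x, ...) {
  cat(sprintf("<daily_stream> %d individuals, %d days, measures: %s\n",
              length(x$ids), length(x$days),
              paste(names(x$events), collapse = ", ")))
  invisible(x)
}

#' Sampling-period tallies for one dyad
#'
#' Counts, over the sampling periods (days) in which at least one member
#' was identified: `x` (days associated), `y_a` (only A identified),
#' `y_b` (only B identified) and `y_ab` (both identified but not
#' associated). Days on which neither member was identified contribute to
#' no field.
#'
#' @param stream a `daily_stream` (single-measure or `"all"`).
#' @param member_a,member_b the dyad's ids.
#' @param measure which event stream to tally (required if the stream
#'   holds several).
#' @return named integer vector `c(x, y_a, y_b, y_ab)`.
#' @export
tally_counts <- function(stream, member_a, member_b, measure = NULL) {
  if (is.null(measure)) {
    if (length(stream$events) != 1L) {
      stop_dyadnet("association", "measure must be named for multi-measure streams")
    }
    measure <- names(stream$events)
  }
  pa <- match(member_a, stream$ids); pb <- match(member_b, stream$ids)
  if (is.na(pa) || is.na(pb)) {
    stop_dyadnet("association", "dyad members not in stream roster")
  }
  k <- which((stream$dyads$member_a == member_a & stream$dyads$member_b == member_b) |
             (stream$dyads$member_a == member_b & stream$dyads$member_b == member_a))
  ev <- vapply(stream$events[[measure]], function(v) k %in% v, logical(1))
  a_seen <- stream$identified[, pa]
  b_seen <- stream$identified[, pb]
  x <- sum(ev)
  c(x = x,
    y_a = sum(a_seen & !b_seen & !ev),
    y_b = sum(b_seen & !a_seen & !ev),
    y_ab = sum(a_seen & b_seen) - x)
}

#' Simple-ratio association index
#'
#' `x / (x + y_ab + y_a + y_b)`: the fraction of sampling periods a dyad
#' was observed associated among the periods in which at least one member
#' was identified. Ranges from 0 (never observed together) to 1 (always
#' observed together). A dyad whose members were never identified has a
#' zero denominator and scores 0 (flagged via the `"zero_denominator"`
#' attribute).
#'
#' @param counts named vector or list with `x`, `y_a`, `y_b`, `y_ab`.
#' @return the index in `[0, 1]`.
#' @export
simple_ratio <- function(counts) {
  x <- counts[["x"]]; den <- x + counts[["y_a"]] + counts[["y_b"]] + counts[["y_ab"]]
  if (any(c(x, counts[["y_a"]], counts[["y_b"]], counts[["y_ab"]]) < 0)) {
    stop_dyadnet("association", "negative sampling count")
  }
  if (den == 0) {
    out <- 0
    attr(out, "zero_denominator") <- TRUE
    return(out)
  }
  x / den
}

# Vectorized tallies for every dyad of a stream: K x 5 matrix with
# columns x, y_a, y_b, y_ab, denominator.
tally_all <- function(stream, measure) {
  idf <- stream$identified
  n_seen <- colSums(idf)
  both <- crossprod(idf)                       # days both identified
  K <- nrow(stream$dyads)
  x <- tabulate(unlist(stream$events[[measure]], use.names = FALSE), nbins = K)
  pa <- stream$pa; pb <- stream$pb
  both_k <- both[cbind(pa, pb)]
  y_a <- n_seen[pa] - both_k
  y_b <- n_seen[pb] - both_k
  y_ab <- both_k - x
  cbind(x = x, y_a = y_a, y_b = y_b, y_ab = y_ab,
        denominator = x + y_a + y_b + y_ab)
}

#' Simple-ratio association matrix
#'
#' @param records a `focal_records` table (one group).
#' @param roster the group's active roster.
#' @param measure `"party10m"`, `"direct1m"` or `"grooming"`.
#' @param identified_rule see [binarize_daily()].
#' @return an `association_matrix`: symmetric numeric matrix of SRI values
#'   with the canonical id order as dimnames, `NA` diagonal, and
#'   attributes `measure` and `zero_denominator` (logical vector over
#'   dyads in row-major upper-triangle order).
#' @export
build_association_matrix <- function(records, roster, measure,
                                     identified_rule = "inclusive") {
  stream <- binarize_daily(records, roster, "all",
                           identified_rule = identified_rule)
  association_matrix_from_stream(stream, measure)
}

association_matrix_from_stream <- function(stream, measure) {
  tl <- tally_all(stream, measure)
  sri <- ifelse(tl[, "denominator"] > 0, tl[, "x"] / tl[, "denominator"], 0)
  n <- length(stream$ids)
  m <- matrix(NA_real_, n, n, dimnames = list(stream$ids, stream$ids))
  m[cbind(stream$pa, stream$pb)] <- sri
  m[cbind(stream$pb, stream$pa)] <- sri
  attr(m, "measure") <- measure
  attr(m, "zero_denominator") <- tl[, "denominator"] == 0
  class(m) <- c("association_matrix", "matrix")
  m
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> measure %s, %d individuals, mean SRI %.3f\n",
              attr(x, "measure"), nrow(x),
              mean(x[upper.tri(x)], na.rm = TRUE)))
  invisible(x)
}

#' Write / read an association matrix as delimited text
#'
#' Square matrix with an id header row and column.
#'
#' @param m an `association_matrix`.
#' @param path file path.
#' @param sep field separator.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_association_matrix <- function(m, path, sep = ",") {
  out <- data.frame(id = rownames(m), unclass(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_matrix
#' @param measure measure label to attach on read.
#' @export
read_association_matrix <- function(path, measure = NA_character_, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d$id
  m <- vapply(d[, -1, drop = FALSE], as.numeric, numeric(nrow(d)))
  dimnames(m) <- list(ids, ids)
  attr(m, "measure") <- measure
  class(m) <- c("association_matrix", "matrix")
  m
}

#' Dyad table with simple-ratio indices for all three measures
#'
#' One row per unordered within-group dyad, members in canonical order,
#' with sex type, kinship, age difference and the SRI on each stream plus
#' its shared denominator. Multiple groups are row-bound.
#'
#' @param records a `focal_records` table.
#' @param roster a `roster` (all groups; excluded individuals dropped
#'   internally).
#' @param identified_rule see [binarize_daily()].
#' @return a `dyad_table` with columns `sri_party`, `sri_direct`,
#'   `sri_groom`, `denominator`, `zero_denominator`.
#' @export
build_dyad_table <- function(records, roster, identified_rule = "inclusive") {
  groups <- unique(roster$group_id[!roster$excluded])
  parts <- lapply(groups, function(g) {
    r <- active_roster(roster, g)
    stream <- binarize_daily(records, r, "all",
                             identified_rule = identified_rule)
    tab <- stream$dyads
    tl_p <- tally_all(stream, "party10m")
    tl_d <- tally_all(stream, "direct1m")
    tl_g <- tally_all(stream, "grooming")
    tab$sri_party <- ifelse(tl_p[, "denominator"] > 0,
                            tl_p[, "x"] / tl_p[, "denominator"], 0)
    tab$sri_direct <- ifelse(tl_d[, "denominator"] > 0,
                             tl_d[, "x"] / tl_d[, "denominator"], 0)
    tab$sri_groom <- ifelse(tl_g[, "denominator"] > 0,
                            tl_g[, "x"] / tl_g[, "denominator"], 0)
    tab$denominator <- tl_p[, "denominator"]
    tab$zero_denominator <- tl_p[, "denominator"] == 0
    tab
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Split a response into hurdle parts
#'
#' The hurdle decomposition models yes/no association first (binomial),
#' then the magnitude of the nonzero associations (beta). `occurrence` is
#' 1 where the SRI exceeds 0; the magnitude table holds exactly the
#' positive-SRI dyads.
#'
#' @param dyads a `dyad_table` from [build_dyad_table()].
#' @param measure `"party10m"`, `"direct1m"` or `"grooming"`.
#' @return list with `occurrence` (the dyad table plus an `occurrence`
#'   0/1 column) and `magnitude` (rows with positive SRI, plus a
#'   `magnitude` column).
#' @export
hurdle_split <- function(dyads, measure) {
  col <- c(party10m = "sri_party", direct1m = "sri_direct",
           grooming = "sri_groom")[[measure]]
  occ <- dyads
  occ$occurrence <- as.integer(dyads[[col]] > 0)
  mag <- dyads[dyads[[col]] > 0, , drop = FALSE]
  mag$magnitude <- mag[[col]]
  rownames(mag) <- NULL
  if (nrow(mag) == 0L) {
    warn_dyadnet("association",
                 "all SRI values are zero for %s; magnitude stage is empty",
                 measure)
  }
  list(occurrence = occ, magnitude = mag)
}
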