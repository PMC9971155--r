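#' Enumerate all unordered within-group dyads
#'
#' Every pair of non-excluded individuals in one group forms a dyad; for a
#' roster of n subjects there are n(n-1)/2 of them. Members are stored in
#' canonical (lexicographic) order, and each dyad carries its sex type
#' (`FF`, `MF`, `MM` — mixed pairs are always labelled `MF`), maternal
#' kinship, absolute age difference in decimal years, and group id.
#'
#' @param roster a `roster`; all rows must share one `group_id` and
#'   excluded individuals must already be removed (see [active_roster()]).
#' @return a `dyad_table` data frame with columns `member_a`, `member_b`,
#'   `sex_type`, `kin`, `age_diff`, `group_id`.
#' @export
enumerate_dyads <- function(roster) {
  if (nrow(roster) < 2L) {
    stop_dyadnet("dyads", "need at least 2 individuals, got %d", nrow(roster))
  }
  if (length(unique(roster$group_id)) != 1L) {
    stop_dyadnet("dyads", "all individuals must share one group_id")
  }
  if (any(roster$excluded)) {
    stop_dyadnet("dyads", "excluded individuals present; use active_roster()")
  }
  ord <- order(roster$id)
  r <- roster[ord, , drop = FALSE]
  n <- nrow(r)
  cmb <- utils::combn(n, 2L)
  ia <- cmb[1L, ]; ib <- cmb[2L, ]
  sex_pair <- paste0(pmin(r$sex[ia], r$sex[ib]), pmax(r$sex[ia], r$sex[ib]))
  sex_type <- c(FF = "FF", FM = "MF", MM = "MM")[sex_pair]
  d <- data.frame(
    member_a = r$id[ia], member_b = r$id[ib],
    sex_type = unname(sex_type),
    kin = maternal_kin(r$id[ia], r$id[ib], r),
    age_diff = abs(r$age_years[ia] - r$age_years[ib]),
    group_id = r$group_id[1L],
    stringsAsFactors = FALSE
  )
  class(d) <- c("dyad_table", "data.frame")
  attr(d, "ids") <- r$id
  d
}

#' Dyad counts by sex type
#'
#' @param dyads a `dyad_table`.
#' @return named integer vector with counts for `FF`, `MF`, `MM` and
#'   `total`.
#' @export
dyad_counts <- function(dyads) {
  tab <- table(factor(dyads$sex_type, levels = c("FF", "MF", "MM")))
  c(FF = unname(tab["FF"]), MF = unname(tab["MF"]), MM = unname(tab["MM"]),
    total = nrow(dyads))
}

#' @export
print.dyad_table <- function(x, ...) {
  cnt <- dyad_counts(x)
  cat(sprintf("<dyad_table> %d dyads (FF %d, MF %d, MM %d), %d kin\n",
              cnt["total"], cnt["FF"], cnt["MF"], cnt["MM"], sum(x$kin)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
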