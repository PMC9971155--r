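test_that("roster validation enforces id uniqueness, sex codes and ages", {
  expect_error(roster(c("A", "A"), c("F", "M"), c(5, 6), "g", c("L1", "L2")),
               "duplicate id")
  expect_error(roster(c("A", "B"), c("F", "X"), c(5, 6), "g", c("L1", "L2")),
               "sex code")
  expect_error(roster(c("A", "B"), c("F", "M"), c(-1, 6), "g", c("L1", "L2")),
               "age")
})

test_that("roster I/O flags under-age individuals instead of dropping them", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,age,group,maternal_line",
               "A,F,10,g1,L1", "B,M,3.5,g1,L2", "C,F,25,g1,L1"), tmp)
  r <- load_roster(tmp)
  expect_equal(nrow(r), 3)
  expect_equal(r$id[r$excluded], "B")
  expect_equal(nrow(active_roster(r)), 2)
  expect_match(run_log(r), "B", all = FALSE)
  # boundary: exactly 4 years is retained
  writeLines(c("id,sex,age,group,maternal_line", "D,F,4,g1,L1",
               "E,M,6,g1,L2"), tmp)
  expect_false(any(load_roster(tmp)$excluded))
})

test_that("empty roster file loads to an empty roster with a warning", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("id,sex,age,group,maternal_line", tmp)
  expect_warning(r <- load_roster(tmp), "empty")
  expect_equal(nrow(r), 0)
})

test_that("missing roster columns are reported by name", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,group", "A,F,g1"), tmp)
  expect_error(load_roster(tmp), "maternal_line")
})

test_that("roster round-trips through delimited text", {
  r <- toy_roster(3, 4)
  tmp <- tempfile(fileext = ".csv")
  write_roster(r, tmp)
  r2 <- load_roster(tmp)
  expect_equal(r2$id, r$id)
  expect_equal(r2$age_years, r$age_years)
  expect_equal(r2$maternal_line, r$maternal_line)
})

test_that("focal record validation catches self-association and unknown ids", {
  r <- toy_roster(2, 2)
  expect_error(
    toy_records(list(list("2013-07-01", "G101", c("G101", "G102"))), r),
    "own associate")
  expect_error(
    toy_records(list(list("2013-07-01", "G101", c("X9"))), r),
    "X9")
})

test_that("1 m ids missing from 10 m are promoted with a logged warning", {
  r <- toy_roster(2, 2)
  rec <- focal_records("2013-07-01", "G101",
                       within10m = list("G102"),
                       within1m = list(c("G102", "G103")),
                       grooming = list(character()), roster = r)
  w10 <- strsplit(rec$within10m, ";")[[1]]
  expect_setequal(w10, c("G102", "G103"))
  expect_match(run_log(rec), "promoted", all = FALSE)
})

test_that("records outside the study window are excluded with a warning", {
  r <- toy_roster(2, 2)
  expect_warning(
    rec <- focal_records(c("2013-07-01", "2013-10-01"), c("G101", "G102"),
                         within10m = list("G102", "G101"),
                         within1m = list(character(), character()),
                         grooming = list(character(), character()),
                         roster = r,
                         study_window = c("2013-07-01", "2013-09-30")),
    "study window")
  expect_equal(nrow(rec), 1)
})

test_that("focal records round-trip through delimited text", {
  r <- toy_roster(3, 3)
  rec <- random_records(r, n_days = 5, seed = 11)
  tmp <- tempfile(fileext = ".csv")
  write_focal_records(rec, tmp)
  rec2 <- load_focal_records(tmp, r)
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("focal_summary reproduces per-individual sampling effort", {
  r <- toy_roster(1, 1)
  rows <- c(rep("A", 3), rep("B", 2))
  rec <- focal_records(rep("2013-07-01", 5),
                       c(rep("G101", 3), rep("G102", 2)),
                       within10m = rep(list(character()), 5),
                       within1m = rep(list(character()), 5),
                       grooming = rep(list(character()), 5), roster = r)
  fs <- focal_summary(rec)
  expect_equal(fs$n_records, 5)
  expect_equal(unname(fs$per_individual), c(3, 2))
  expect_equal(fs$mean_per_individual, 2.5)
})

test_that("dyad enumeration matches n(n-1)/2 with consistent sex-type counts", {
  set.seed(4)
  for (rep in 1:20) {
    n_m <- sample(0:6, 1); n_f <- sample(0:6, 1)
    if (n_m + n_f < 2) next
    r <- toy_roster(n_m, n_f)
    d <- enumerate_dyads(r)
    n <- n_m + n_f
    expect_equal(nrow(d), n * (n - 1) / 2)
    cnt <- dyad_counts(d)
    expect_equal(unname(cnt["total"]),
                 unname(cnt["FF"] + cnt["MF"] + cnt["MM"]))
    expect_equal(unname(cnt["MM"]), n_m * (n_m - 1) / 2)
    expect_equal(unname(cnt["FF"]), n_f * (n_f - 1) / 2)
    expect_equal(unname(cnt["MF"]), n_m * n_f)
    expect_true(all(d$member_a < d$member_b))
    expect_true(all(d$age_diff >= 0))
  }
})

test_that("dyad enumeration rejects degenerate or mixed-group rosters", {
  r1 <- toy_roster(1, 0)
  expect_error(enumerate_dyads(r1), "at least 2")
  r2 <- rbind(toy_roster(1, 1, group = "g1"), toy_roster(1, 1, group = "g2"))
  class(r2) <- c("roster", "data.frame")
  expect_error(enumerate_dyads(r2), "one group_id")
})

test_that("maternal kinship covers mother-offspring and maternal siblings only", {
  # maternal_line holds the mother's id; A is mother of B and C
  r <- roster(c("A", "B", "C", "D"), c("F", "F", "M", "F"),
              c(30, 10, 8, 20), "g1",
              maternal_line = c("FOUNDER", "A", "A", "FOUNDER2"))
  d <- enumerate_dyads(r)
  kin_pairs <- d[d$kin, c("member_a", "member_b")]
  got <- paste(kin_pairs$member_a, kin_pairs$member_b)
  expect_setequal(got, c("A B", "A C", "B C"))
  # two individuals sharing a line are kin even in the smallest roster
  r2 <- roster(c("A", "B"), c("F", "F"), c(9, 11), "g1", c("L1", "L1"))
  expect_true(enumerate_dyads(r2)$kin)
})
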