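test_that("daily binarization scores a dyad once per day and shares identification", {
  r <- toy_roster(2, 2)  # G101, G102 males; G103, G104 females
  rec <- toy_records(list(
    list("2013-07-01", "G101", "G102"),       # A sees B twice that day
    list("2013-07-01", "G101", "G102"),
    list("2013-07-01", "G103", character()),
    list("2013-07-02", "G101", character()),  # both focal, never together
    list("2013-07-02", "G102", character())
  ), r)
  st <- binarize_daily(rec, r, "all")
  k_ab <- which(st$dyads$member_a == "G101" & st$dyads$member_b == "G102")
  expect_equal(st$events$party10m[[1]], k_ab)     # one event despite 2 samples
  expect_equal(st$events$party10m[[2]], integer())
  cnt <- tally_counts(st, "G101", "G102", "party10m")
  expect_equal(unname(cnt["x"]), 1)
  expect_equal(unname(cnt["y_ab"]), 1)
  # G103 was focal on day 1 only: identified there even with no associates
  expect_true(st$identified["2013-07-01", "G103"])
  expect_false(st$identified["2013-07-02", "G103"])
})

test_that("grooming events imply direct and party events on nested streams", {
  r <- toy_roster(2, 2)
  rec <- toy_records(list(
    list("2013-07-01", "G101", "G102", "G102", "G102")
  ), r)
  st <- binarize_daily(rec, r, "all")
  k <- which(st$dyads$member_a == "G101" & st$dyads$member_b == "G102")
  expect_equal(st$events$grooming[[1]], k)
  expect_equal(st$events$direct1m[[1]], k)
  expect_equal(st$events$party10m[[1]], k)
})

test_that("the focal-only identification rule narrows the denominators", {
  r <- toy_roster(2, 2)
  rec <- toy_records(list(
    list("2013-07-01", "G101", "G102")  # G102 seen only as an associate
  ), r)
  st_inc <- binarize_daily(rec, r, "all", identified_rule = "inclusive")
  st_foc <- binarize_daily(rec, r, "all", identified_rule = "focal_only")
  expect_true(st_inc$identified["2013-07-01", "G102"])
  expect_false(st_foc$identified["2013-07-01", "G102"])
  # the dyad day still counts as associated under both rules
  cnt <- tally_counts(st_foc, "G101", "G102", "party10m")
  expect_equal(unname(cnt["x"]), 1)
})

test_that("binarize_daily rejects empty input", {
  r <- toy_roster(2, 2)
  rec <- toy_records(list(list("2013-07-01", "G101", "G102")), r)
  expect_error(binarize_daily(rec[0, ], r), "empty")
})

test_that("hand-tallied sampling counts and simple ratio match the worked case", {
  # 5 days: associated on 2, both seen apart on 1, only A seen on 1,
  # neither seen on 1 -> x=2, y_ab=1, y_a=1, y_b=0 and SRI = 0.5
  r <- toy_roster(2, 2)
  rec <- toy_records(list(
    list("2013-07-01", "G101", "G102"),
    list("2013-07-02", "G102", "G101"),
    list("2013-07-03", "G101", character()), list("2013-07-03", "G102", "G103"),
    list("2013-07-04", "G101", "G103"),
    list("2013-07-05", "G103", "G104")
  ), r)
  st <- binarize_daily(rec, r, "all")
  cnt <- tally_counts(st, "G101", "G102", "party10m")
  expect_equal(unname(cnt), c(2, 1, 0, 1))
  expect_equal(simple_ratio(cnt), 0.5)
})

test_that("simple ratio handles saturation, zeros and invalid input", {
  expect_equal(simple_ratio(c(x = 5, y_a = 0, y_b = 0, y_ab = 0)), 1)
  expect_equal(simple_ratio(c(x = 0, y_a = 0, y_b = 0, y_ab = 3)), 0)
  z <- simple_ratio(c(x = 0, y_a = 0, y_b = 0, y_ab = 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_denominator"))
  expect_error(simple_ratio(c(x = -1, y_a = 0, y_b = 0, y_ab = 0)),
               "negative")
})

test_that("pipeline SRIs equal the brute-force oracle on random fixtures", {
  set.seed(77)
  for (case in 1:40) {
    n_m <- sample(1:3, 1); n_f <- sample(1:3, 1)
    if (n_m + n_f < 2) next
    r <- toy_roster(n_m, n_f)
    rec <- random_records(r, n_days = sample(2:10, 1), seed = 1000 + case)
    for (measure in c("party10m", "direct1m", "grooming")) {
      m <- build_association_matrix(rec, r, measure)
      for (k in which(upper.tri(m))) {
        idx <- arrayInd(k, dim(m))
        ora <- oracle_sri(rec, measure, rownames(m)[idx[1]],
                          colnames(m)[idx[2]])
        expect_identical(unname(m[k]), ora$sri)
      }
    }
  }
})

test_that("record order does not affect any SRI", {
  r <- toy_roster(3, 3)
  rec <- random_records(r, n_days = 8, seed = 5)
  m1 <- build_association_matrix(rec, r, "party10m")
  perm <- rec[sample(nrow(rec)), ]
  class(perm) <- class(rec)
  m2 <- build_association_matrix(perm, r, "party10m")
  expect_equal(unclass(m1), unclass(m2))
})

test_that("nested streams give monotone SRIs and symmetric matrices in [0,1]", {
  sim <- simulate_study(test_config(seed = 13))
  dt <- build_dyad_table(sim$records, sim$roster)
  expect_true(all(dt$sri_groom <= dt$sri_direct + 1e-12))
  expect_true(all(dt$sri_direct <= dt$sri_party + 1e-12))
  expect_true(all(dt$sri_party >= 0 & dt$sri_party <= 1))
  r1 <- active_roster(sim$roster, "g1")
  m <- build_association_matrix(sim$records, r1, "party10m")
  expect_true(all(is.na(diag(m))))
  expect_equal(unclass(m), t(unclass(m)))
})

test_that("association matrices round-trip through delimited text", {
  sim <- simulate_study(test_config(seed = 8))
  r1 <- active_roster(sim$roster, "g1")
  m <- build_association_matrix(sim$records, r1, "party10m")
  tmp <- tempfile(fileext = ".csv")
  write_association_matrix(m, tmp)
  m2 <- read_association_matrix(tmp, "party10m")
  expect_equal(unclass(m)[upper.tri(m)], unclass(m2)[upper.tri(m2)],
               tolerance = 1e-12)
})

test_that("hurdle split partitions dyads by zero vs positive index", {
  sim <- simulate_study(test_config(seed = 30, beta0 = -3.5))
  dt <- build_dyad_table(sim$records, sim$roster)
  hs <- hurdle_split(dt, "direct1m")
  expect_equal(nrow(hs$occurrence), nrow(dt))
  expect_setequal(hs$occurrence$occurrence, c(0, 1))
  expect_equal(sum(hs$occurrence$occurrence), nrow(hs$magnitude))
  expect_true(all(hs$magnitude$magnitude > 0))
  # sparse regime: most direct-proximity indices are zero
  expect_lt(nrow(hs$magnitude), nrow(dt) / 2)
  # degenerate: all zero -> empty magnitude with warning
  dt0 <- dt; dt0$sri_direct <- 0
  expect_warning(hs0 <- hurdle_split(dt0, "direct1m"), "zero")
  expect_equal(nrow(hs0$magnitude), 0)
})
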