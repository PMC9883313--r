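# Association criteria, the restriction filter and half-weight indices.

toy_roster <- function() {
  # six individuals with constructed sighting histories across 3 years
  mk <- function(ind, dates) data.frame(
    individual = ind, event = paste0("e", dates), ordinal = 1,
    date = as.Date(dates), stringsAsFactors = FALSE)
  rbind(
    mk("A", c("1997-06-01", "1997-06-02", "1998-06-01", "2010-06-01",
              "2010-06-02")),                      # 5 days, both years
    mk("B", c("1997-06-01", "1998-06-01", "1998-06-02", "1998-06-03",
              "2010-06-01")),                      # 5 days, both years
    mk("C", c("1997-06-01", "1997-06-02", "1997-06-03", "2010-06-01")),
                                                   # only 4 days
    mk("D", c("1998-06-01", "1998-06-02", "1998-06-03", "1998-06-04",
              "1998-06-05", "1998-06-06")),        # 6 days, middle year only
    mk("E", c("1997-06-01", "1997-06-02", "1997-06-03", "1997-06-04",
              "1997-06-05")),                      # 5 days, missing 2010
    mk("F", c("1997-06-01", "2010-06-01"))         # both years, 2 days
  )
}

test_that("the restriction filter keeps exactly the hand-enumerated set", {
  rec <- toy_roster()
  expect_identical(
    restrict_individuals(rec, min_days = 5, require_years = c(1997, 2010)),
    c("A", "B"))
  expect_identical(restrict_individuals(rec, min_days = 6), "D")
  expect_identical(
    restrict_individuals(rec, min_days = 2, require_years = c(1997, 2010)),
    c("A", "B", "C", "F"))
  expect_warning(restrict_individuals(rec, min_days = 10), "no individuals")
})

test_that("the three criteria apply their rules and nest", {
  rec <- data.frame(
    individual = c("A", "B"), event = "enc1", ordinal = c(10, 20),
    date = as.Date("2005-07-01"))
  prob <- daily_associations(rec, "probabilistic", threshold = 14)
  frame <- daily_associations(rec, "same_frame")
  enc <- daily_associations(rec, "encounter")
  expect_equal(nrow(prob$edges[[1]]), 1)   # lag 10 <= 14
  expect_equal(nrow(frame$edges[[1]]), 0)
  expect_equal(nrow(enc$edges[[1]]), 1)
  # a lag beyond the threshold drops the probabilistic association
  expect_equal(nrow(daily_associations(
    rec, "probabilistic", threshold = 9)$edges[[1]]), 0)
  # the comparison is inclusive of the threshold lag
  expect_equal(nrow(daily_associations(
    rec, "probabilistic", threshold = 10)$edges[[1]]), 1)

  same_frame_rec <- data.frame(
    individual = c("A", "B"), event = "enc1", ordinal = 7,
    date = as.Date("2005-07-01"))
  for (crit in c("probabilistic", "same_frame", "encounter")) {
    a <- daily_associations(same_frame_rec, crit,
                            threshold = if (crit == "probabilistic") 1)
    expect_equal(nrow(a$edges[[1]]), 1)
  }

  apart <- data.frame(
    individual = c("A", "B"), event = c("enc1", "enc2"), ordinal = 1,
    date = as.Date("2005-07-01"))
  for (crit in c("probabilistic", "same_frame", "encounter")) {
    a <- daily_associations(apart, crit,
                            threshold = if (crit == "probabilistic") 99)
    expect_equal(nrow(a$edges[[1]]), 0)
  }
  expect_error(daily_associations(rec, "probabilistic"), "threshold")
})

test_that("criterion nesting holds dyad-by-dyad on simulated data", {
  rec <- simulate_identifications(simulation_config(n_days = 10), seed = 21)
  a_f <- daily_associations(rec, "same_frame")
  a_p <- daily_associations(rec, "probabilistic", threshold = 10)
  a_e <- daily_associations(rec, "encounter")
  key <- function(e) paste(e[, 1], e[, 2])
  for (k in seq_along(a_f$days)) {
    expect_true(all(key(a_f$edges[[k]]) %in% key(a_p$edges[[k]])))
    expect_true(all(key(a_p$edges[[k]]) %in% key(a_e$edges[[k]])))
  }
  h_f <- hwi_matrix(a_f)$hwi
  h_p <- hwi_matrix(a_p)$hwi
  h_e <- hwi_matrix(a_e)$hwi
  expect_true(all(h_f <= h_p + 1e-12))
  expect_true(all(h_p <= h_e + 1e-12))
})

test_that("raising the probabilistic threshold never lowers any HWI", {
  rec <- simulate_identifications(simulation_config(n_days = 10), seed = 33)
  prev <- NULL
  for (thr in c(1, 5, 10, 25)) {
    h <- hwi_matrix(daily_associations(rec, "probabilistic",
                                       threshold = thr))$hwi
    if (!is.null(prev)) expect_true(all(prev <= h + 1e-12))
    prev <- h
  }
})

test_that("half-weight index reproduces hand-computed tallies", {
  # day 1: A and B seen and associated; day 2: only A seen
  assoc <- daily_associations(make_fixture("hwi-toy"), "same_frame")
  hw <- hwi_matrix(assoc)
  expect_equal(hw$hwi["A", "B"], 2 / 3)   # x=1, yA=1 -> 1/(1 + 1/2)
  expect_equal(hw$x["A", "B"], 1)
  expect_equal(hw$ya["A", "B"], 1)
  expect_equal(hw$yab["A", "B"], 0)

  # always together and associated -> HWI 1
  rec <- data.frame(individual = rep(c("A", "B"), 3),
                    event = rep(c("e1", "e2", "e3"), each = 2),
                    ordinal = 1,
                    date = rep(as.Date("2001-06-01") + 0:2, each = 2))
  hw2 <- hwi_matrix(daily_associations(rec, "same_frame"))
  expect_equal(hw2$hwi["A", "B"], 1)

  # never jointly sampled -> structural zero
  rec3 <- data.frame(individual = c("A", "B"), event = c("e1", "e2"),
                     ordinal = 1, date = as.Date(c("2001-06-01",
                                                   "2001-06-02")))
  hw3 <- hwi_matrix(daily_associations(rec3, "encounter"))
  expect_equal(hw3$hwi["A", "B"], 0)
  expect_true(hw3$structural_zero["A", "B"])
})

test_that("HWI matrix matches the brute-force per-dyad oracle", {
  rec <- simulate_identifications(
    simulation_config(n_individuals = 18, n_units = 3, n_days = 12),
    seed = 14)
  assoc <- daily_associations(rec, "probabilistic", threshold = 8)
  hw <- hwi_matrix(assoc)
  oracle <- brute_hwi(assoc, assoc$ids)
  expect_equal(hw$hwi, oracle, tolerance = 1e-12)
  # structural sanity
  expect_true(isSymmetric(hw$hwi))
  expect_true(all(diag(hw$hwi) == 0))
  expect_true(all(hw$hwi >= 0 & hw$hwi <= 1))
  # every value equals its own tally formula
  den <- hw$x + hw$yab + (hw$ya + hw$yb) / 2
  expect_equal(hw$hwi[den > 0],
               (hw$x / den)[den > 0], tolerance = 1e-12)
})

test_that("restricting to an ID set drops other individuals entirely", {
  rec <- simulate_identifications(simulation_config(n_days = 8), seed = 2)
  keep <- sort(unique(rec$individual))[1:10]
  assoc <- daily_associations(rec, "encounter", ids = keep)
  expect_true(all(unlist(assoc$seen) %in% keep))
  hw <- hwi_matrix(assoc)
  expect_identical(hw$ids, keep)
})
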