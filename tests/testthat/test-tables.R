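test_that("validation accepts the two-center worked example and orders centers", {
  d <- two_center_fixture()
  expect_s3_class(d, "mc_tables")
  expect_equal(n_centers(d), 2)
  expect_equal(d$y1, c(30L, 45L))
  expect_equal(d$n1, c(100L, 100L))
  expect_equal(d$y2, c(50L, 75L))
  expect_equal(d$t, c(80L, 120L))
  expect_equal(d$n, c(200L, 200L))
  # unsorted long input comes back sorted by center
  long <- data.frame(center = c(2, 2, 1, 1), treat = c(1, 2, 1, 2),
                     y = c(45, 75, 30, 50), n = 100)
  expect_equal(validate_tables(long)$y1, c(30L, 45L))
})

test_that("validation rejects malformed records and names the center", {
  expect_error(validate_tables(
    data.frame(center = 1, treat = 1, y = 5, n = 10)), "two arms")
  expect_error(validate_tables(
    data.frame(center = c(1, 1, 1), treat = c(1, 1, 2),
               y = c(5, 6, 7), n = 10)), "duplicated")
  expect_error(mc_tables(y1 = 11, n1 = 10, y2 = 5, n2 = 10), "center 1")
  expect_error(validate_tables(
    data.frame(center = c(1, 1), treat = c(1, 2), y = c(2.5, 3), n = 10)),
    "non-integer")
  # boundary counts (all successes / all failures) are legal
  d <- mc_tables(y1 = c(10, 0), n1 = c(10, 10), y2 = c(0, 5),
                 n2 = c(10, 10))
  expect_s3_class(d, "mc_tables")
})

test_that("sample odds ratios match direct arithmetic and symmetry", {
  d <- two_center_fixture()
  expect_equal(sample_or(d)[1], (30 * 50) / (70 * 50))
  expect_equal(sample_or(d)[2], (45 * 25) / (55 * 75))
  # identical arms give OR = 1
  same <- mc_tables(y1 = c(7, 12), n1 = c(20, 30), y2 = c(7, 12),
                    n2 = c(20, 30))
  expect_equal(sample_or(same), c(1, 1))
  # zero cell with the default 0.5 correction, on corrected cells
  z <- mc_tables(y1 = 0, n1 = 10, y2 = 5, n2 = 10)
  expect_equal(sample_or(z), (0.5 * 5.5) / (10.5 * 5.5))
  expect_true(is.infinite(
    sample_or(mc_tables(5, 10, 0, 10),
              continuity_policy(scope = "never"))))
})

test_that("arm swap inverts the odds ratio exactly", {
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(10:100, 3); n2 <- sample(10:100, 3)
    y1 <- pmax(1, pmin(n1 - 1, rbinom(3, n1, 0.4)))
    y2 <- pmax(1, pmin(n2 - 1, rbinom(3, n2, 0.3)))
    d <- mc_tables(y1, n1, y2, n2)
    swapped <- mc_tables(y2, n2, y1, n1)
    expect_equal(sample_or(swapped), 1 / sample_or(d))
  }
})

test_that("log-OR variance is the sum of reciprocal cells and scales as 1/c", {
  d <- two_center_fixture()
  expect_equal(log_or_variance(d)[1], 1 / 30 + 1 / 70 + 1 / 50 + 1 / 50)
  expect_equal(log_or_variance(d)[2], 1 / 45 + 1 / 55 + 1 / 75 + 1 / 25)
  doubled <- mc_tables(2 * d$y1, 2 * d$n1, 2 * d$y2, 2 * d$n2)
  expect_equal(log_or_variance(doubled), log_or_variance(d) / 2)
})

test_that("Mantel-Haenszel pooling matches arithmetic and stays within the OR range", {
  d <- two_center_fixture()
  expect_equal(mh_or(d), (7.5 + 5.625) / (17.5 + 20.625))
  # single stratum reduces to the sample OR
  one <- mc_tables(30, 100, 50, 100)
  expect_equal(mh_or(one), sample_or(one))
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(20:80, 4); n2 <- sample(20:80, 4)
    y1 <- pmax(1, pmin(n1 - 1, rbinom(4, n1, 0.5)))
    y2 <- pmax(1, pmin(n2 - 1, rbinom(4, n2, 0.35)))
    d <- mc_tables(y1, n1, y2, n2)
    ors <- sample_or(d, continuity_policy(scope = "never"))
    expect_gte(mh_or(d), min(ors))
    expect_lte(mh_or(d), max(ors))
  }
})

test_that("CSV round-trip is lossless and bad files are rejected", {
  spec <- scenario_spec(K = 8, design = "among", level = 2,
                        sigma_u2 = 0.5, sigma_b2 = 0.4, seed = 3)
  d <- simulate_tables(spec, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_tables_csv(d, path)
  back <- read_tables_csv(path)
  expect_equal(back$y1, d$y1)
  expect_equal(back$y2, d$y2)
  expect_equal(back$n1, d$n1)
  expect_equal(back$n2, d$n2)
  # whitespace-delimited input is auto-detected
  ws <- tempfile(fileext = ".txt")
  writeLines(c("center treat y n", "1 1 30 100", "1 2 50 100",
               "2 1 45 100", "2 2 75 100"), ws)
  expect_equal(read_tables_csv(ws)$y1, c(30L, 45L))
  # three arms in one center
  bad <- tempfile(fileext = ".csv")
  writeLines(c("center,treat,y,n", "1,1,3,10", "1,2,4,10", "1,2,5,10",
               "2,1,3,10", "2,2,4,10"), bad)
  expect_error(read_tables_csv(bad))
  # header mismatch
  hdr <- tempfile(fileext = ".csv")
  writeLines(c("site,arm,y,n", "1,1,3,10"), hdr)
  expect_error(read_tables_csv(hdr), "expected columns")
})
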