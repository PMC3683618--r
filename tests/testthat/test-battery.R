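test_that("battery construction validates cells and names offenders", {
  m <- matrix(c(1, 0, 2, 1, 0, 1, 0, 1), 2, 4)
  expect_error(tom_battery(m), "row 1, column DB")
  expect_error(tom_battery(matrix(1, 2, 5)), "4 .* or 6")
  ok <- tom_battery(matrix(c(1, 0, 1, 1, 0, 0, 1, 0), 2, 4))
  expect_identical(dim(ok$responses), c(2L, 4L))
  expect_identical(colnames(ok$responses), TOM_SCALE_TASKS)
})

test_that("covariate validation enforces domains and names the row", {
  covs <- toy_covariates(3)
  resp <- matrix(1L, 3, 6)
  bad <- covs; bad$birth_order[2] <- bad$n_siblings[2] + 2
  expect_error(tom_battery(resp, bad), "row 2, column birth_order")
  bad <- covs; bad$gender[3] <- 2
  expect_error(tom_battery(resp, bad), "gender")
  bad <- covs; bad$age_months[1] <- 0
  expect_error(tom_battery(resp, bad), "age_months")
  bad <- covs[, -2]
  expect_error(tom_battery(resp, bad), "missing covariate column")
})

test_that("children with identical demographics get indices 1, 2, ...", {
  covs <- toy_covariates(4)
  covs[2, c("age_months", "gender", "n_siblings", "birth_order")] <-
    covs[4, c("age_months", "gender", "n_siblings", "birth_order")] <-
    list(80, 1, 1, 2)
  b <- tom_battery(matrix(1L, 4, 6), covs)
  expect_identical(b$covariates$disambiguation_index[c(2, 4)], c(1L, 2L))
  expect_identical(b$covariates$disambiguation_index[c(1, 3)], c(1L, 1L))
})

test_that("battery tables round-trip exactly through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (seed in c(1, 2)) {
    b <- simulate_battery(sim_config(n_children = 200, seed = seed))
    write_battery_table(b, path)
    b2 <- read_battery_table(path)
    expect_identical(b2$responses, b$responses)
    expect_equal(b2$covariates, b$covariates)
  }
})

test_that("an empty battery writes a header-only file and reads back", {
  path <- withr::local_tempfile(fileext = ".csv")
  b <- tom_battery(matrix(integer(0), 0, 6), toy_covariates(1)[0, ])
  write_battery_table(b, path)
  expect_length(readLines(path), 1L)
  b2 <- read_battery_table(path)
  expect_identical(nrow(b2$responses), 0L)
})

test_that("reading a table with a missing column fails by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  b <- simulate_battery(sim_config(n_children = 5, seed = 3))
  write_battery_table(b, path)
  tab <- read.csv(path)
  write.csv(tab[, setdiff(names(tab), "KA")], path, row.names = FALSE)
  expect_error(read_battery_table(path), "KA")
})

test_that("aggregate summary counts passes and successive violations", {
  s <- battery_summary(matrix(1L, 5, 4))
  expect_equal(unname(s$pass_counts), c(5, 5, 5, 5))
  expect_equal(unname(s$violations), c(0, 0, 0))
  s1 <- battery_summary(matrix(c(0L, 1L, 0L, 1L), 1, 4))
  expect_equal(unname(s1$pass_counts), c(0, 1, 0, 1))
  expect_equal(unname(s1$violations), c(1, 0, 1))
})

test_that("summary is invariant to child (row) reordering", {
  b <- simulate_battery(sim_config(seed = 8))
  x <- b$responses
  set.seed(4)
  for (i in 1:5) {
    s <- battery_summary(x[sample(nrow(x)), ])
    expect_identical(s$pass_counts, battery_summary(x)$pass_counts)
    expect_identical(s$violations, battery_summary(x)$violations)
  }
})

test_that("the fixture matrix reproduces every published aggregate", {
  b <- fixture_battery()
  s <- battery_summary(b)
  expect_identical(s$n_children, 76L)
  expect_equal(unname(s$pass_counts), c(62, 56, 48, 36))
  expect_equal(unname(s$violations), c(6, 11, 10))
  expect_identical(fixture_battery()$responses, b$responses)  # deterministic
  expect_equal(oracle_fom(b$responses), 27L)
})
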