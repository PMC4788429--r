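# Synthetic-data generator: counts, determinism, analytic limits, noise
# calibration and file round-trips.

test_that("dataset size and determinism follow the options", {
  p <- observer_params(1)
  d1 <- simulate_dataset(params = p, options = sim_options(reps = 5, seed = 3))
  expect_equal(nrow(d1), 198 * 5)
  d2 <- simulate_dataset(params = p, options = sim_options(reps = 5, seed = 3))
  expect_identical(d1, d2)
  d3 <- simulate_dataset(params = p, options = sim_options(reps = 5, seed = 4))
  expect_false(identical(d1, d3))
  # displacement vector connects pre- and postsaccadic positions
  par <- d1$displacement_axis == "parallel"
  expect_equal(d1$post_x - d1$pre_x, ifelse(par, d1$displacement_size, 0))
  expect_equal(d1$post_y - d1$pre_y, ifelse(par, 0, d1$displacement_size))
  expect_equal(d1$err_x, d1$resp_x - d1$pre_x)
  # 4-or-5 repetition draw
  d4 <- simulate_dataset(params = p,
                         options = sim_options(vary_reps = TRUE, seed = 9))
  reps <- table(.saccadeCI_condkey(d4))
  expect_true(all(reps %in% 4:5))
})

test_that("veridical-segregation limit reproduces the presaccadic position exactly", {
  d <- simulate_dataset(small_design(c(-5, 0, 5)), veridical_params(),
                        sim_options(reps = 3, seed = 2))
  expect_lt(max(abs(d$err_x)), 1e-4)
  expect_lt(max(abs(d$err_y)), 1e-4)
})

test_that("noiseless full-integration responses stay between pre- and postsaccadic positions", {
  p <- equal_integration_params(sigma = 1e-4)
  d <- simulate_dataset(small_design(c(-5, -1, 1, 5)), p,
                        sim_options(reps = 3, seed = 6))
  along <- ifelse(d$displacement_axis == "parallel", d$err_x, d$err_y)
  frac <- along / d$displacement_size
  expect_true(all(frac > -1e-4 & frac < 1 + 1e-4))
  # equal sigmas with flat priors -> the midpoint weight 1/2
  expect_equal(mean(frac), 0.5, tolerance = 1e-3)
})

test_that("sampled visual percepts carry the parameterized noise", {
  p <- observer_params(1)  # sigma_v at 1000 ms is 1.42 deg
  d <- simulate_dataset(params = p,
                        options = sim_options(reps = 40, seed = 12,
                                              diagnostics = TRUE))
  d <- d[d$viewing_ms == 1000, ]
  resid <- c(ave(d$v_x, .saccadeCI_condkey(d), FUN = function(x) x - mean(x)),
             ave(d$v_y, .saccadeCI_condkey(d), FUN = function(x) x - mean(x)))
  expect_equal(sd(resid), 1.42, tolerance = 0.03)
})

test_that("datasets round-trip through CSV and malformed files are reported by row and field", {
  p <- observer_params(2)
  d <- simulate_dataset(small_design(), p, sim_options(reps = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back, d, tolerance = 1e-12)

  empty <- d[0, ]
  write_dataset(empty, path)
  expect_equal(nrow(read_dataset(path)), 0)

  write_dataset(d, path)
  lines <- readLines(path)
  lines[4] <- sub(",([-0-9.]+)$", ",oops", lines[4])
  writeLines(lines, path)
  expect_error(read_dataset(path), "row 3, field 'err_y'")
})

test_that("simulate_trial produces a single canonical-frame record", {
  cond <- pooled_design()[17, ]
  rec <- withr::with_seed(8, simulate_trial(cond, observer_params(3)))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$target, cond$target)
  expect_equal(rec$err_x, rec$resp_x - rec$pre_x)
  expect_error(simulate_trial(cond, observer_params(3),
                              sim_options(rule = "bogus")), "arg")
})
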