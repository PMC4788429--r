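test_that("canonical layout is an equilateral triangle with 15-deg sides", {
  lay <- target_layout()
  expect_equal(lay$ft, c(0, 0))
  expect_equal(lay$st, c(15, 0))
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_equal(d(lay$ft, lay$st), 15, tolerance = 1e-12)
  expect_lt(abs(d(lay$ft, lay$nt) - 15), 1e-9)
  expect_lt(abs(d(lay$st, lay$nt) - 15), 1e-9)
  expect_equal(lay$nt[1], (lay$ft[1] + lay$st[1]) / 2)
  expect_equal(lay$nt[2], 15 * sin(pi / 3), tolerance = 1e-12)
  expect_equal(target_position(c("nt", "ft")),
               rbind(lay$nt, lay$ft))
})

test_that("full factorial design has 792 distinct trial types", {
  d <- full_design()
  expect_equal(nrow(d), 792)
  expect_equal(nrow(unique(d)), 792)
  # brute-force cell count: fixing target, viewing and configuration leaves
  # the 11 x 2 displacement factorial
  sub <- d[d$target == "ft" & d$viewing_ms == 50 &
             d$saccade_dir == "right" & d$nt_side == "above", ]
  expect_equal(nrow(sub), 22)
  expect_equal(sort(unique(d$displacement_size)),
               sort(displacement_levels()))
})

test_that("pooling reduces the design to 198 conditions and is idempotent", {
  pooled <- pool_conditions(full_design())
  expect_equal(nrow(pooled), 198)
  expect_equal(nrow(unique(pooled)), 198)
  expect_equal(pool_conditions(pooled), pooled)
  expect_equal(pooled_design(), pooled)
  # both zero-displacement cells (one per axis) are kept distinct
  expect_equal(sum(pooled$displacement_size == 0), 3 * 2 * 3)
})

test_that("pooling transform mirrors non-canonical configurations and is an involution", {
  expect_equal(pooling_transform(c(3, 2), "right", "above"),
               matrix(c(3, 2), 1))
  expect_equal(pooling_transform(c(3, 2), "left", "above"),
               matrix(c(-3, 2), 1))
  expect_equal(pooling_transform(c(3, 2), "right", "below"),
               matrix(c(3, -2), 1))
  set.seed(4)
  pts <- matrix(rnorm(40, sd = 8), ncol = 2)
  for (dir in c("left", "right")) {
    for (side in c("above", "below")) {
      once <- pooling_transform(pts, dir, side)
      expect_equal(pooling_transform(once, dir, side), pts)
    }
  }
  expect_error(pooling_transform(c(1, 2), "up"), "saccade_dir")
})

test_that("localization error is signed response minus presaccadic position", {
  expect_equal(localization_error(c(5, 5), c(5, 5)), matrix(c(0, 0), 1))
  # 1 deg in the saccade direction -> +1 on x
  expect_equal(localization_error(c(1, 0), c(0, 0)), matrix(c(1, 0), 1))
  # 2 deg below the target -> -2 on y
  expect_equal(localization_error(c(7.5, 10.99), c(7.5, 12.99)),
               matrix(c(0, -2), 1))
  r <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(localization_error(r, c(1, 1)),
               matrix(c(0, 1, 2, 3), 2, byrow = TRUE))
})

test_that("designs export to plain CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(pooled_design(), path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 198)
  expect_equal(names(back),
               c("target", "displacement_size", "displacement_axis",
                 "viewing_ms"))
  expect_true(all(back$target %in% c("ft", "st", "nt")))
})
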