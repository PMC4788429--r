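# Core model math: percept construction, conditional estimates, marginal
# likelihoods (against quadrature oracles), the common-cause posterior and
# the response rules.

test_that("foveal shift pulls the percept mean toward the anchor by the shrinkage fraction", {
  # anchor case and the exact shrinkage value sigma^2/(sigma^2 + sigma_f^2)
  expect_equal(foveal_shift(c(0, 0), c(0, 0), 3, 4), matrix(c(0, 0), 1))
  expect_equal(foveal_shift(c(10, 0), c(0, 0), 3, 4),
               matrix(c(10 * 16 / 25, 0), 1))  # = (6.4, 0)
  # vanishing sensory noise leaves the percept at the true position
  expect_equal(foveal_shift(c(10, 5), c(0, 0), 1e-9, 4),
               matrix(c(10, 5), 1), tolerance = 1e-12)
  # result lies on the segment between true position and anchor, per axis
  set.seed(1)
  for (i in 1:10) {
    tp <- rnorm(2, sd = 8); an <- rnorm(2, sd = 8)
    sg <- runif(2, 0.1, 5)
    out <- foveal_shift(tp, an, sg, runif(1, 0.5, 8))
    lo <- pmin(tp, an); hi <- pmax(tp, an)
    expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  }
  expect_error(foveal_shift(c(1, 1), c(0, 0), -1, 4), "strictly positive")
  # literal-ratio mode is capped so the mean cannot overshoot the anchor
  expect_equal(foveal_shift(c(10, 0), c(0, 0), 8, 4, mode = "ratio"),
               matrix(c(0, 0), 1))
})

test_that("integration estimate is the precision-weighted mean of m, v and the prior", {
  p <- base_params(sigma_pi_x = 2, sigma_pi_y = 2, pi_x = 0, pi_y = 0)
  # all sources agree
  expect_equal(integration_estimate(c(0, 0), c(0, 0), p, "ft", 50),
               matrix(c(0, 0), 1))
  # m=(0,0), v=(2,0), prior at 0 with sd 2: x = 2 / (1 + 1 + 0.25)
  expect_equal(integration_estimate(c(0, 0), c(2, 0), p, "ft", 50),
               matrix(c(2 / 2.25, 0), 1))
  # flat prior and equal sigmas -> midpoint of m and v
  pf <- base_params(sigma_pi_x = 1e9, sigma_pi_y = 1e9)
  expect_equal(integration_estimate(c(0, 0), c(2, 2), pf, "st", 300),
               matrix(c(1, 1), 1), tolerance = 1e-6)
})

test_that("segregation estimate combines m with the prior only", {
  p <- base_params(sigma_mx_ft = 2, sigma_my_ft = 2,
                   sigma_pi_x = 2, sigma_pi_y = 2, pi_x = 0, pi_y = 0)
  # equal precisions give the midpoint of m and the prior center
  expect_equal(segregation_estimate(c(4, 0), p, "ft"), matrix(c(2, 0), 1))
  expect_equal(segregation_estimate(c(0, 0), p, "ft"), matrix(c(0, 0), 1))
  pf <- base_params(sigma_pi_x = 1e9, sigma_pi_y = 1e9)
  expect_equal(segregation_estimate(c(3, -2), pf, "nt"),
               matrix(c(3, -2), 1), tolerance = 1e-6)
})

test_that("closed-form marginal likelihoods match numerical quadrature", {
  # independent oracle: integrate the 1D integrand over the latent
  # position (finite window around all mass; infinite limits let the
  # quadrature miss narrow peaks)
  quad_common_1d <- function(m, v, pi0, sm, sv, sp) {
    w <- 12 * max(sm, sv, sp)
    integrate(function(s) dnorm(m, s, sm) * dnorm(v, s, sv) * dnorm(s, pi0, sp),
              min(m, v, pi0) - w, max(m, v, pi0) + w,
              rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)$value
  }
  quad_single_1d <- function(x, pi0, sx, sp) {
    w <- 12 * max(sx, sp)
    integrate(function(s) dnorm(x, s, sx) * dnorm(s, pi0, sp),
              min(x, pi0) - w, max(x, pi0) + w,
              rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)$value
  }
  set.seed(7)
  for (i in 1:20) {
    p <- base_params(
      sigma_mx_ft = runif(1, 0.3, 4), sigma_my_ft = runif(1, 0.3, 4),
      sigma_v_300 = runif(1, 0.3, 4),
      sigma_pi_x = runif(1, 2, 25), sigma_pi_y = runif(1, 2, 25),
      pi_x = rnorm(1, 7, 4), pi_y = rnorm(1, 5, 4))
    m <- rnorm(2, c(0, 0), 3); v <- rnorm(2, c(2, 0), 3)
    lc <- likelihood_common(m, v, p, "ft", 300)
    ls <- likelihood_separate(m, v, p, "ft", 300)
    oc <- quad_common_1d(m[1], v[1], p[["pi_x"]], p[["sigma_mx_ft"]],
                         p[["sigma_v_300"]], p[["sigma_pi_x"]]) *
          quad_common_1d(m[2], v[2], p[["pi_y"]], p[["sigma_my_ft"]],
                         p[["sigma_v_300"]], p[["sigma_pi_y"]])
    os <- quad_single_1d(m[1], p[["pi_x"]], p[["sigma_mx_ft"]], p[["sigma_pi_x"]]) *
          quad_single_1d(v[1], p[["pi_x"]], p[["sigma_v_300"]], p[["sigma_pi_x"]]) *
          quad_single_1d(m[2], p[["pi_y"]], p[["sigma_my_ft"]], p[["sigma_pi_y"]]) *
          quad_single_1d(v[2], p[["pi_y"]], p[["sigma_v_300"]], p[["sigma_pi_y"]])
    expect_lt(abs(lc - oc) / oc, 1e-8)
    expect_lt(abs(ls - os) / os, 1e-8)
  }
})

test_that("common-cause likelihood is symmetric and falls with percept discrepancy", {
  # exchanging (m - pi) and (v - pi) together with sigma_m and sigma_v
  p1 <- base_params(sigma_mx_ft = 1.3, sigma_my_ft = 1.3, sigma_v_50 = 2.6,
                    pi_x = 3, pi_y = 1)
  p2 <- base_params(sigma_mx_ft = 2.6, sigma_my_ft = 2.6, sigma_v_50 = 1.3,
                    pi_x = 3, pi_y = 1)
  m <- c(4, 2); v <- c(1, 0)
  expect_equal(likelihood_common(m, v, p1, "ft", 50),
               likelihood_common(v, m, p2, "ft", 50), tolerance = 1e-12)
  # separate-cause likelihood is even around the prior center
  pi0 <- c(3, 1)
  expect_equal(likelihood_separate(m, v, p1, "ft", 50),
               likelihood_separate(2 * pi0 - m, 2 * pi0 - v, p1, "ft", 50),
               tolerance = 1e-12)
  # p(mv|C) decreases monotonically with |m - v|, all else fixed
  deltas <- seq(0, 8, by = 0.5)
  lik <- likelihood_common(cbind(3 - deltas / 2, rep(1, length(deltas))),
                           cbind(3 + deltas / 2, rep(1, length(deltas))),
                           p1, "ft", 50)
  expect_true(all(diff(lik) < 0))
})

test_that("common-cause posterior behaves as the causal-inference account predicts", {
  p <- base_params(p_c = 0.3, pi_x = 3, pi_y = 1)
  m <- c(4, 2); v <- c(1, 0)
  expect_equal(posterior_common(m, v, base_params(p_c = 0), "ft", 50), 0)
  expect_equal(posterior_common(m, v, base_params(p_c = 1), "ft", 50), 1)
  # an uninformative visual percept leaves the posterior at the prior
  pw <- base_params(p_c = 0.3, sigma_v_50 = 1e6)
  expect_equal(posterior_common(m, v, pw, "ft", 50), 0.3, tolerance = 1e-3)
  # with m at the prior center, moving v away cannot raise the posterior
  pv <- base_params(p_c = 0.5, pi_x = 0, pi_y = 0)
  offs <- seq(0, 6, by = 0.25)
  post <- posterior_common(matrix(0, length(offs), 2), cbind(offs, 0),
                           pv, "ft", 50)
  expect_true(all(diff(post) <= 1e-12))
  expect_true(all(post >= 0 & post <= 1))
})

test_that("response rules coincide at degenerate priors and mix convexly otherwise", {
  m <- c(1, 2); v <- c(3, 0)
  for (pc in c(0, 1)) {
    p <- base_params(p_c = pc)
    r1 <- respond_mixture(m, v, p, "st", 300)
    r2 <- respond_selection(m, v, p, "st", 300)
    r3 <- respond_matching(m, v, p, "st", 300, u = 0.42)
    expect_equal(r1$s_hat_x, r2$s_hat_x)
    expect_equal(r1$s_hat_y, r3$s_hat_y)
    target <- if (pc == 1) c(r1$s_common_x, r1$s_common_y)
              else c(r1$s_sep_x, r1$s_sep_y)
    expect_equal(c(r1$s_hat_x, r1$s_hat_y), target)
  }
  # mixture response is a per-axis convex combination of the two estimates
  set.seed(11)
  for (i in 1:20) {
    p <- base_params(p_c = runif(1, 0.05, 0.95))
    r <- respond_mixture(rnorm(2, 0, 3), rnorm(2, 2, 3), p, "nt", 1000)
    for (ax in c("x", "y")) {
      lo <- min(r[[paste0("s_common_", ax)]], r[[paste0("s_sep_", ax)]])
      hi <- max(r[[paste0("s_common_", ax)]], r[[paste0("s_sep_", ax)]])
      expect_true(r[[paste0("s_hat_", ax)]] >= lo - 1e-12 &&
                    r[[paste0("s_hat_", ax)]] <= hi + 1e-12)
    }
    expect_equal(r$s_hat_x,
                 r$p_common * r$s_common_x + (1 - r$p_common) * r$s_sep_x)
  }
})

test_that("selection thresholds at 0.5 and matching matches choice frequency to the posterior", {
  p <- base_params(p_c = 0.5, pi_x = 0, pi_y = 0)
  # clearly consistent percepts -> integrate; clearly discrepant -> segregate
  near <- respond_selection(c(0.1, 0), c(0.3, 0), p, "ft", 1000)
  expect_gt(near$p_common, 0.5)
  expect_equal(near$s_hat_x, near$s_common_x)
  far <- respond_selection(c(-4, 0), c(7, 0), p, "ft", 1000)
  expect_lt(far$p_common, 0.5)
  expect_equal(far$s_hat_x, far$s_sep_x)

  # matching: empirical integration frequency converges to p(C|mv)
  m <- c(0, 0); v <- c(2.4, 0)
  one <- respond_matching(m, v, p, "ft", 1000, u = 0.5)
  p_star <- one$p_common
  n <- 1e5
  u <- withr::with_seed(99, runif(n))
  many <- respond_matching(matrix(m, n, 2, byrow = TRUE),
                           matrix(v, n, 2, byrow = TRUE), p,
                           rep("ft", n), rep(1000, n), u = u)
  freq <- mean(many$s_hat_x == many$s_common_x)
  se <- sqrt(p_star * (1 - p_star) / n)
  expect_lt(abs(freq - p_star), 4 * se)
})
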