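# Simulation-based binned likelihood: PMF construction, objective
# determinism, engine agreement and discrimination of wrong parameters.

test_that("condition PMFs are normalized, floored and converge to the analytic limit", {
  cfg <- fit_config(n_sims = 20000, seed = 2, likelihood_mode = "binned_2d")
  pd <- pooled_design()
  cond <- pd[pd$target == "ft", ][1, ]
  # pure segregation with a flat prior: err_x is exactly N(0, sigma_mx)
  p <- base_params(p_c = 0, sigma_pi_x = 1e6, sigma_pi_y = 1e6,
                   sigma_f = 1e6, sigma_mx_ft = 1.5)
  pmf <- condition_response_pmf(cond, p, "mixture", cfg)
  tab <- as.data.frame(pmf)
  # total mass: occupied bins plus the floor spread over the empty ones
  total <- sum(tab$prob) +
    (pmf$nbins^2 - nrow(tab)) * pmf$floor_prob / pmf$nbins^2
  expect_lt(abs(total - 1), 1e-12)
  expect_true(all(tab$prob >= pmf$floor_prob / pmf$nbins^2))
  # moments of the binned x-marginal against the analytic distribution
  mu <- sum(tab$prob * tab$err_x)
  s <- sqrt(sum(tab$prob * (tab$err_x - mu)^2))
  expect_equal(mu, 0, tolerance = 0.04)
  expect_equal(s, 1.5, tolerance = 0.04)
  # an error far outside the simulated support still has floor mass
  expect_equal(pmf_prob(pmf, c(19.99, -19.99)),
               pmf$floor_prob / pmf$nbins^2)
})

test_that("dataset log-likelihood is deterministic and computed identically by both engines", {
  p <- observer_params(1)
  d <- simulate_dataset(small_design(), p, sim_options(reps = 3, seed = 21))
  for (mode in c("binned_per_axis", "binned_2d")) {
    cfg <- fit_config(n_sims = 400, seed = 5, likelihood_mode = mode)
    ll1 <- dataset_loglik(d, p, "mixture", cfg)
    ll2 <- dataset_loglik(d, p, "mixture", cfg)
    expect_identical(ll1, ll2)
    llr <- dataset_loglik(d, p, "mixture", cfg, engine = "r")
    expect_equal(llr, ll1, tolerance = 1e-10)
    # matching rule consumes the shared uniform draws identically
    expect_equal(dataset_loglik(d, p, "matching", cfg, engine = "r"),
                 dataset_loglik(d, p, "matching", cfg), tolerance = 1e-10)
  }
  expect_identical(dataset_loglik(d[0, ], p), 0)
})

test_that("generating parameters beat grossly perturbed ones", {
  p <- observer_params(1)
  wrong <- unclass(p)
  wrong[grep("^sigma_[mv]", names(wrong))] <-
    wrong[grep("^sigma_[mv]", names(wrong))] * 10
  wrong <- as_model_params(wrong)
  for (seed in 1:3) {
    d <- simulate_dataset(params = p, options = sim_options(reps = 5,
                                                            seed = seed))
    cfg <- fit_config(n_sims = 1000, seed = seed + 50)
    expect_gt(dataset_loglik(d, p, "mixture", cfg),
              dataset_loglik(d, wrong, "mixture", cfg))
  }
})

test_that("fit configurations round-trip through YAML", {
  cfg <- fit_config(n_sims = 1234, bin_width = 0.2, n_restarts = 7,
                    likelihood_mode = "binned_2d", seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fit_config(cfg, path)
  expect_equal(read_fit_config(path), cfg)
  expect_error(fit_config(n_sims = 10), "at least 100")
  expect_error(fit_config(floor_prob = 0), "floor_prob")
})

test_that("trials outside the factorial design are rejected", {
  p <- observer_params(1)
  d <- simulate_dataset(small_design(), p, sim_options(reps = 1, seed = 1))
  d$displacement_size[3] <- 7
  expect_error(dataset_loglik(d, p), "outside the pooled design")
})
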