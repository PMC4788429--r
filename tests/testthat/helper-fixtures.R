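# Shared fixtures: a neutral parameter baseline that individual tests
# override, plus small design subsets.

base_params <- function(...) {
  p <- c(sigma_mx_ft = 1, sigma_mx_st = 1, sigma_mx_nt = 1,
         sigma_my_ft = 1, sigma_my_st = 1, sigma_my_nt = 1,
         sigma_v_50 = 1, sigma_v_300 = 1, sigma_v_1000 = 1,
         sigma_f = 4, sigma_pi_x = 10, sigma_pi_y = 10,
         pi_x = 7.5, pi_y = 5, p_c = 0.5)
  over <- c(...)
  p[names(over)] <- over
  as_model_params(p)
}

# Parameters that make the generative model essentially veridical
# segregation: no integration, flat priors, tiny memory noise.
veridical_params <- function(sigma_m = 1e-6) {
  base_params(p_c = 0, sigma_pi_x = 1e6, sigma_pi_y = 1e6, sigma_f = 1e6,
              sigma_mx_ft = sigma_m, sigma_mx_st = sigma_m,
              sigma_mx_nt = sigma_m, sigma_my_ft = sigma_m,
              sigma_my_st = sigma_m, sigma_my_nt = sigma_m)
}

# Full-integration limit with equal weights on m and v and flat priors.
equal_integration_params <- function(sigma = 1) {
  base_params(p_c = 1, sigma_pi_x = 1e6, sigma_pi_y = 1e6, sigma_f = 1e6,
              sigma_mx_ft = sigma, sigma_mx_st = sigma, sigma_mx_nt = sigma,
              sigma_my_ft = sigma, sigma_my_st = sigma, sigma_my_nt = sigma,
              sigma_v_50 = sigma, sigma_v_300 = sigma, sigma_v_1000 = sigma)
}

# Grouping key for pooled conditions in a trial dataset.
.saccadeCI_condkey <- function(d) {
  paste(d$target, d$displacement_size, d$displacement_axis, d$viewing_ms)
}

# A small design subset: all targets/axes/viewings at a few displacements.
small_design <- function(displacements = c(0, 1, -1)) {
  d <- pooled_design()
  d[d$displacement_size %in% displacements, , drop = FALSE]
}
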