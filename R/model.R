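# Causal-inference core: percept construction with foveal bias, the two
# conditional position estimates, the marginal likelihoods of (m, v) under
# common vs. independent causes, the common-cause posterior, and the three
# response rules. All functions are vectorized over trials (n x 2 matrices).

#' Foveal bias of a percept mean
#'
#' A percept is modeled as the Bayesian combination of an accurate sensory
#' signal (SD `sigma` per axis) with an isotropic foveal prior of width
#' `sigma_f` centered at `anchor` (the fixation target for the memory
#' percept, the saccade landing point for the visual percept). The percept
#' mean is therefore the true position pulled toward the anchor, per axis,
#' by the shrinkage fraction `sigma^2 / (sigma^2 + sigma_f^2)`; the
#' percept's dispersion stays at the parameterized `sigma`.
#'
#' `mode = "ratio"` evaluates the literal fraction `sigma^2 / sigma_f^2`
#' (capped at 1 so the mean stays on the segment), an alternative reading
#' retained for sensitivity analysis.
#'
#' @param true_pos,anchor 2D points or `n x 2` matrices, degrees.
#' @param sigma Sensory SD: scalar, length-2 `(x, y)`, or `n x 2` matrix.
#' @param sigma_f Foveal prior width (deg), scalar.
#' @param mode `"bayes"` (default) or `"ratio"`.
#' @return `n x 2` matrix of percept means (deg).
#' @examples
#' foveal_shift(c(10, 0), c(0, 0), sigma = 3, sigma_f = 4)  # (6.4, 0)
#' @export
foveal_shift <- function(true_pos, anchor, sigma, sigma_f,
                         mode = c("bayes", "ratio")) {
  mode <- match.arg(mode)
  pos <- as_xy(true_pos)
  anc <- as_xy(anchor)
  n <- max(nrow(pos), nrow(anc))
  if (nrow(pos) == 1L) pos <- pos[rep(1L, n), , drop = FALSE]
  if (nrow(anc) == 1L) anc <- anc[rep(1L, n), , drop = FALSE]
  if (is.null(dim(sigma))) {
    sigma <- if (length(sigma) == 1L) matrix(sigma, n, 2L)
             else if (length(sigma) == 2L) matrix(sigma, n, 2L, byrow = TRUE)
             else stop("'sigma' must be scalar, length 2, or an n x 2 matrix")
  }
  if (any(sigma <= 0) || sigma_f <= 0)
    stop("'sigma' and 'sigma_f' must be strictly positive")
  w <- switch(mode,
              bayes = sigma^2 / (sigma^2 + sigma_f^2),
              ratio = pmin(sigma^2 / sigma_f^2, 1))
  pos + (anc - pos) * w
}

# Per-axis marginal likelihood of (m, v) under a common cause: the integral
# over s of N(m; s, sm) N(v; s, sv) N(s; pi, sp) in closed form.
.lik_common_1d <- function(m, v, pi0, sm, sv, sp) {
  sm2 <- sm^2; sv2 <- sv^2; sp2 <- sp^2
  D <- sm2 * sv2 + sm2 * sp2 + sv2 * sp2
  q <- ((m - v)^2 * sp2 + (m - pi0)^2 * sv2 + (v - pi0)^2 * sm2) / D
  exp(-0.5 * q) / (2 * base::pi * sqrt(D))
}

# Per-axis marginal likelihood under independent causes: product of the two
# single-signal marginals N(m; pi, sqrt(sm^2+sp^2)) N(v; pi, sqrt(sv^2+sp^2)).
.lik_separate_1d <- function(m, v, pi0, sm, sv, sp) {
  dnorm(m, pi0, sqrt(sm^2 + sp^2)) * dnorm(v, pi0, sqrt(sv^2 + sp^2))
}

# Resolve per-trial sigmas/prior given params and condition labels.
.trial_sigmas <- function(params, target, viewing_ms, n) {
  target <- recycle_to(target, n)
  viewing_ms <- recycle_to(viewing_ms, n)
  list(sm = .sigma_m(params, target),
       sv = .sigma_v(params, viewing_ms),
       sp = c(params[["sigma_pi_x"]], params[["sigma_pi_y"]]),
       pi0 = .pi_pos(params))
}

#' Marginal likelihood of the percept pair under a common cause
#'
#' Evaluates, per axis, the closed-form marginal likelihood of the percepts
#' `(m, v)` under the hypothesis that both arise from one target position
#' drawn from the allocentric prior, and returns the product over the two
#' axes, `p(mv|C)`.
#'
#' @param m,v Percepts: 2D points or `n x 2` matrices, canonical frame (deg).
#' @param params A [model_params()] vector.
#' @param target Target label(s): `"ft"`, `"st"` or `"nt"`.
#' @param viewing_ms Viewing duration(s): 50, 300 or 1000.
#' @return Numeric vector of strictly positive likelihood densities.
#' @export
likelihood_common <- function(m, v, params, target, viewing_ms) {
  params <- as_model_params(params)
  m <- as_xy(m); v <- as_xy(v)
  n <- nrow(m)
  s <- .trial_sigmas(params, target, viewing_ms, n)
  .lik_common_1d(m[, 1], v[, 1], s$pi0[1], s$sm[, 1], s$sv, s$sp[1]) *
    .lik_common_1d(m[, 2], v[, 2], s$pi0[2], s$sm[, 2], s$sv, s$sp[2])
}

#' Marginal likelihood of the percept pair under independent causes
#'
#' Under segregation each percept is marginalized over its own target
#' position, giving per axis a product of two Gaussians with variances
#' `sigma_m^2 + sigma_pi^2` and `sigma_v^2 + sigma_pi^2`; the value returned
#' is the product over axes, `p(mv|C-bar)`.
#'
#' @inheritParams likelihood_common
#' @return Numeric vector of strictly positive likelihood densities.
#' @export
likelihood_separate <- function(m, v, params, target, viewing_ms) {
  params <- as_model_params(params)
  m <- as_xy(m); v <- as_xy(v)
  n <- nrow(m)
  s <- .trial_sigmas(params, target, viewing_ms, n)
  .lik_separate_1d(m[, 1], v[, 1], s$pi0[1], s$sm[, 1], s$sv, s$sp[1]) *
    .lik_separate_1d(m[, 2], v[, 2], s$pi0[2], s$sm[, 2], s$sv, s$sp[2])
}

#' Posterior probability of a common cause
#'
#' Combines the two marginal likelihoods with the prior `p_c`:
#' `p(C|mv) = p_c p(mv|C) / (p_c p(mv|C) + (1 - p_c) p(mv|C-bar))`.
#' Degenerate priors return the constant (`0` for `p_c = 0`, `1` for
#' `p_c = 1`) rather than evaluating a 0/0 expression.
#'
#' @inheritParams likelihood_common
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
posterior_common <- function(m, v, params, target, viewing_ms) {
  params <- as_model_params(params)
  pc <- params[["p_c"]]
  if (pc == 0) return(rep(0, nrow(as_xy(m))))
  if (pc == 1) return(rep(1, nrow(as_xy(m))))
  lc <- likelihood_common(m, v, params, target, viewing_ms)
  ls <- likelihood_separate(m, v, params, target, viewing_ms)
  pc * lc / (pc * lc + (1 - pc) * ls)
}

#' Conditional position estimates
#'
#' `integration_estimate` is the mean of the common-cause posterior over the
#' target position: per axis the precision-weighted mean of the memory
#' percept, the visual percept and the allocentric prior center.
#' `segregation_estimate` drops the visual percept and combines the memory
#' percept with the prior only.
#'
#' @inheritParams likelihood_common
#' @return `n x 2` matrix of position estimates (deg, canonical frame).
#' @export
integration_estimate <- function(m, v, params, target, viewing_ms) {
  params <- as_model_params(params)
  m <- as_xy(m); v <- as_xy(v)
  s <- .trial_sigmas(params, target, viewing_ms, nrow(m))
  est <- function(ax) {
    wm <- 1 / s$sm[, ax]^2; wv <- 1 / s$sv^2; wp <- 1 / s$sp[ax]^2
    (m[, ax] * wm + v[, ax] * wv + s$pi0[ax] * wp) / (wm + wv + wp)
  }
  cbind(est(1), est(2))
}

#' @rdname integration_estimate
#' @export
segregation_estimate <- function(m, params, target) {
  params <- as_model_params(params)
  m <- as_xy(m)
  n <- nrow(m)
  target <- recycle_to(target, n)
  sm <- .sigma_m(params, target)
  sp <- c(params[["sigma_pi_x"]], params[["sigma_pi_y"]])
  pi0 <- .pi_pos(params)
  est <- function(ax) {
    wm <- 1 / sm[, ax]^2; wp <- 1 / sp[ax]^2
    (m[, ax] * wm + pi0[ax] * wp) / (wm + wp)
  }
  cbind(est(1), est(2))
}

# Shared response machinery: posterior, conditional estimates, and the
# response under one of the three rules. u supplies the uniform draws for
# probability matching (required only for that rule).
respond_core <- function(m, v, params, target, viewing_ms, rule, u = NULL) {
  m <- as_xy(m); v <- as_xy(v)
  n <- nrow(m)
  p_common <- posterior_common(m, v, params, target, viewing_ms)
  s_common <- integration_estimate(m, v, params, target, viewing_ms)
  s_sep <- segregation_estimate(m, params, target)
  s_hat <- switch(rule,
    mixture = p_common * s_common + (1 - p_common) * s_sep,
    selection = {
      pick <- p_common >= 0.5  # ties resolve to the common-cause estimate
      pick * s_common + (1 - pick) * s_sep
    },
    matching = {
      if (is.null(u)) u <- runif(n)
      pick <- u < p_common
      pick * s_common + (1 - pick) * s_sep
    },
    stop("unknown response rule: ", rule))
  out <- data.frame(p_common = p_common,
                    s_common_x = s_common[, 1], s_common_y = s_common[, 2],
                    s_sep_x = s_sep[, 1], s_sep_y = s_sep[, 2],
                    s_hat_x = s_hat[, 1], s_hat_y = s_hat[, 2])
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Response rules
#'
#' Given a percept pair, each rule turns the common-cause posterior and the
#' two conditional estimates into a single localization response:
#' \describe{
#'   \item{`respond_mixture`}{the statistically optimal rule: the mean of
#'     the mixture posterior, `p(C|mv)` times the integration estimate plus
#'     `1 - p(C|mv)` times the segregation estimate (minimizes expected
#'     squared error).}
#'   \item{`respond_selection`}{picks the estimate of the more probable
#'     causal structure (`p(C|mv) > 0.5` integrates; ties integrate).}
#'   \item{`respond_matching`}{probability matching: integrates with
#'     probability `p(C|mv)`, using the supplied uniform draws `u` (or fresh
#'     draws from the session RNG).}
#' }
#'
#' @inheritParams likelihood_common
#' @param u Optional uniform(0,1) draws, one per trial (matching rule only).
#' @return A `posterior_summary` data.frame with columns `p_common`,
#'   `s_common_x/y`, `s_sep_x/y`, `s_hat_x/y`.
#' @export
respond_mixture <- function(m, v, params, target, viewing_ms) {
  respond_core(m, v, as_model_params(params), target, viewing_ms, "mixture")
}

#' @rdname respond_mixture
#' @export
respond_selection <- function(m, v, params, target, viewing_ms) {
  respond_core(m, v, as_model_params(params), target, viewing_ms, "selection")
}

#' @rdname respond_mixture
#' @export
respond_matching <- function(m, v, params, target, viewing_ms, u = NULL) {
  respond_core(m, v, as_model_params(params), target, viewing_ms, "matching",
               u = u)
}
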