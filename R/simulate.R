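# Synthetic-data generator: trial-level datasets with the statistical
# structure of the SSD experiment, generated from the causal-inference model
# itself under a chosen response rule.

#' Simulation options
#'
#' @param rule Response rule generating the responses: `"mixture"`,
#'   `"selection"` or `"matching"`.
#' @param reps Repetitions per pooled condition (the experiment used 4 or 5
#'   per trial type; pooled over the four screen configurations this yields
#'   roughly 12 per pooled condition per session block).
#' @param vary_reps If `TRUE`, draw 4 or 5 repetitions per condition at
#'   random instead of the fixed `reps`.
#' @param landing_scatter `NULL` (default, off) or a length-2 vector of SDs
#'   (deg, parallel/orthogonal) for trial-to-trial jitter of the saccade
#'   landing point that anchors the foveal bias of `v`. The empirical
#'   saccade-endpoint scatter in this task is about `c(1.27, 0.73)`.
#'   Off by default so the generative model matches the fitted model
#'   exactly, as parameter-recovery analyses require.
#' @param motor_noise SD (deg) of isotropic motor/pointing noise added to
#'   the response; 0 (default) keeps all response variability perceptual.
#' @param foveal_mode Shrinkage convention passed to [foveal_shift()].
#' @param diagnostics If `TRUE`, the sampled internal percepts `m` and `v`
#'   are kept in the dataset (`m_x`, `m_y`, `v_x`, `v_y`).
#' @param seed Integer seed; [simulate_dataset()] is deterministic given it.
#' @return A list of class `"sim_options"`.
#' @export
sim_options <- function(rule = c("mixture", "selection", "matching"),
                        reps = 5L, vary_reps = FALSE, landing_scatter = NULL,
                        motor_noise = 0, foveal_mode = c("bayes", "ratio"),
                        diagnostics = FALSE, seed = 1L) {
  rule <- match.arg(rule)
  foveal_mode <- match.arg(foveal_mode)
  if (reps < 1L) stop("'reps' must be at least 1")
  if (!is.null(landing_scatter) && length(landing_scatter) != 2L)
    stop("'landing_scatter' must be NULL or length 2 (parallel, orthogonal)")
  if (motor_noise < 0) stop("'motor_noise' must be non-negative")
  structure(list(rule = rule, reps = as.integer(reps), vary_reps = vary_reps,
                 landing_scatter = landing_scatter,
                 motor_noise = motor_noise, foveal_mode = foveal_mode,
                 diagnostics = diagnostics, seed = as.integer(seed)),
            class = "sim_options")
}

# Geometry of pooled conditions in the canonical frame: presaccadic target
# position and its postsaccadic (possibly displaced) position.
condition_geometry <- function(conditions, layout = target_layout()) {
  pre <- target_position(conditions$target, layout)
  disp <- matrix(0, nrow(conditions), 2L)
  par <- conditions$displacement_axis == "parallel"
  disp[par, 1] <- conditions$displacement_size[par]
  disp[!par, 2] <- conditions$displacement_size[!par]
  list(pre = pre, post = pre + disp)
}

# Simulate one record per design row using the *current* RNG state.
simulate_records <- function(conditions, params, options) {
  params <- as_model_params(params)
  n <- nrow(conditions)
  layout <- target_layout()
  geom <- condition_geometry(conditions, layout)
  sm <- .sigma_m(params, conditions$target)
  sv <- .sigma_v(params, conditions$viewing_ms)
  sf <- params[["sigma_f"]]

  landing <- matrix(layout$st, n, 2L, byrow = TRUE)
  if (!is.null(options$landing_scatter)) {
    landing[, 1] <- landing[, 1] + rnorm(n, 0, options$landing_scatter[1])
    landing[, 2] <- landing[, 2] + rnorm(n, 0, options$landing_scatter[2])
  }

  m_mean <- foveal_shift(geom$pre, layout$ft, sm, sf, mode = options$foveal_mode)
  v_mean <- foveal_shift(geom$post, landing, cbind(sv, sv), sf,
                         mode = options$foveal_mode)
  m <- m_mean + cbind(rnorm(n, 0, sm[, 1]), rnorm(n, 0, sm[, 2]))
  v <- v_mean + cbind(rnorm(n, 0, sv), rnorm(n, 0, sv))

  resp <- respond_core(m, v, params, conditions$target, conditions$viewing_ms,
                       options$rule, u = runif(n))
  response <- cbind(resp$s_hat_x, resp$s_hat_y)
  if (options$motor_noise > 0)
    response <- response + matrix(rnorm(2 * n, 0, options$motor_noise), n, 2L)
  err <- localization_error(response, geom$pre)

  out <- data.frame(
    target = conditions$target,
    displacement_size = conditions$displacement_size,
    displacement_axis = conditions$displacement_axis,
    viewing_ms = conditions$viewing_ms,
    pre_x = geom$pre[, 1], pre_y = geom$pre[, 2],
    post_x = geom$post[, 1], post_y = geom$post[, 2],
    resp_x = response[, 1], resp_y = response[, 2],
    err_x = err[, 1], err_y = err[, 2])
  if (options$diagnostics) {
    out$m_x <- m[, 1]; out$m_y <- m[, 2]
    out$v_x <- v[, 1]; out$v_y <- v[, 2]
  }
  out
}

#' Simulate a single trial
#'
#' Draws the internal percepts for one pooled condition and produces the
#' model's localization response under the option's response rule. Consumes
#' the session RNG; use [simulate_dataset()] for seeded, reproducible
#' datasets.
#'
#' @param condition One row of [pooled_design()] (or an equivalent list with
#'   fields `target`, `displacement_size`, `displacement_axis`,
#'   `viewing_ms`).
#' @param params A [model_params()] vector.
#' @param options A [sim_options()] list.
#' @return A one-row trial data.frame (see [simulate_dataset()]).
#' @export
simulate_trial <- function(condition, params, options = sim_options()) {
  if (!is.data.frame(condition)) condition <- as.data.frame(condition)
  if (nrow(condition) != 1L) stop("'condition' must be a single trial type")
  simulate_records(condition, params, options)
}

#' Simulate a trial-level SSD dataset
#'
#' Generates `reps` independent trials for every condition in `design` from
#' the generative causal-inference model: percept means with foveal bias
#' (memory anchored at the fixation target on the presaccadic position,
#' vision anchored at the saccade landing point on the displaced position),
#' Gaussian percept noise per the parameter set, and a response from the
#' chosen rule. Deterministic given `options$seed`.
#'
#' @param design A data.frame of pooled conditions, default the full
#'   [pooled_design()] (198 conditions).
#' @param params A [model_params()] vector.
#' @param options A [sim_options()] list.
#' @return A data.frame with one row per trial and columns `target`,
#'   `displacement_size`, `displacement_axis`, `viewing_ms`, `pre_x`,
#'   `pre_y`, `post_x`, `post_y`, `resp_x`, `resp_y`, `err_x`, `err_y`
#'   (plus `m_x`..`v_y` when diagnostics are enabled). Errors are signed in
#'   the canonical frame.
#' @examples
#' d <- simulate_dataset(params = observer_params(1),
#'                       options = sim_options(reps = 2, seed = 42))
#' nrow(d)  # 198 * 2
#' @export
simulate_dataset <- function(design = pooled_design(), params,
                             options = sim_options()) {
  local_seed(options$seed, {
    reps <- if (isTRUE(options$vary_reps))
      sample(4:5, nrow(design), replace = TRUE)
    else rep(options$reps, nrow(design))
    rows <- rep(seq_len(nrow(design)), times = reps)
    out <- simulate_records(design[rows, , drop = FALSE], params, options)
    rownames(out) <- NULL
    out
  })
}

.dataset_numeric_cols <- c("displacement_size", "viewing_ms",
                           "pre_x", "pre_y", "post_x", "post_y",
                           "resp_x", "resp_y", "err_x", "err_y",
                           "m_x", "m_y", "v_x", "v_y")

#' Read / write trial datasets
#'
#' Plain CSV with a header; coordinates in decimal degrees, factors as
#' lowercase strings. The round trip is lossless. `read_dataset` validates
#' the file and reports the first malformed row and field.
#'
#' @param records A trial dataset from [simulate_dataset()] (or of the same
#'   shape).
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   data.frame of trials.
#' @export
write_dataset <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("target", "displacement_size", "displacement_axis",
                "viewing_ms", "pre_x", "pre_y", "post_x", "post_y",
                "resp_x", "resp_y", "err_x", "err_y")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("dataset is missing columns: ", paste(missing, collapse = ", "))
  for (col in intersect(.dataset_numeric_cols, names(raw))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in row %d, field '%s': \"%s\"",
                   bad[1], col, raw[[col]][bad[1]]))
    raw[[col]] <- num
  }
  raw$viewing_ms <- as.integer(raw$viewing_ms)
  raw
}
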