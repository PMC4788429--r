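utils::globalVariables(c("displacement_size", "mean_error", "viewing_ms",
                         "sem", "err_along"))

# Summary analyses: mean localization-error curves against displacement,
# Monte-Carlo curves of the common-cause posterior, and the descriptive
# small-displacement slope.

# Error component along the condition's displacement axis.
.err_along <- function(dataset) {
  ifelse(dataset$displacement_axis == "parallel",
         dataset$err_x, dataset$err_y)
}

#' Mean localization error per condition
#'
#' Groups trials by (target, displacement axis, viewing time, displacement
#' size) and summarizes the signed error component along the displacement
#' axis: its mean, SEM across trials, and trial count.
#'
#' @param dataset A trial dataset in the canonical frame.
#' @return A data.frame of class `"curve_table"` with columns `target`,
#'   `displacement_axis`, `viewing_ms`, `displacement_size`, `mean_error`,
#'   `sem`, `n`.
#' @export
error_curves <- function(dataset) {
  dataset$err_along <- .err_along(dataset)
  grp <- dataset[c("target", "displacement_axis", "viewing_ms",
                   "displacement_size")]
  agg <- aggregate(dataset["err_along"], by = grp, FUN = mean)
  names(agg)[names(agg) == "err_along"] <- "mean_error"
  agg$sem <- aggregate(dataset["err_along"], by = grp,
                       FUN = function(e) sd(e) / sqrt(length(e)))$err_along
  agg$n <- aggregate(dataset["err_along"], by = grp, FUN = length)$err_along
  agg <- agg[order(agg$target, agg$displacement_axis, agg$viewing_ms,
                   agg$displacement_size), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("curve_table", "data.frame")
  agg
}

#' Expected common-cause posterior as a function of displacement
#'
#' For each displacement on the grid, samples percept pairs from the
#' generative model for the given condition cell and averages the
#' common-cause posterior `p(C|mv)` over the draws: the model's predicted
#' displacement-detection curve (its complement is the probability of
#' perceiving the displacement).
#'
#' @param params A [model_params()] vector.
#' @param target `"ft"`, `"st"` or `"nt"`.
#' @param axis `"parallel"` or `"orthogonal"`.
#' @param viewing_ms 50, 300 or 1000.
#' @param displacements Numeric grid of displacement sizes (deg).
#' @param n_sims Monte-Carlo draws per displacement.
#' @param seed Integer seed.
#' @return A data.frame with columns `displacement_size` and `p_common`.
#' @export
pcurve <- function(params, target, axis, viewing_ms,
                   displacements = displacement_levels(), n_sims = 2000L,
                   seed = 1L) {
  params <- as_model_params(params)
  conds <- data.frame(target = target,
                      displacement_size = rep(displacements, each = n_sims),
                      displacement_axis = axis,
                      viewing_ms = as.integer(viewing_ms))
  rec <- local_seed(seed, {
    simulate_records(conds, params,
                     sim_options(rule = "mixture", diagnostics = TRUE))
  })
  pc <- posterior_common(cbind(rec$m_x, rec$m_y), cbind(rec$v_x, rec$v_y),
                         params, rec$target, rec$viewing_ms)
  data.frame(displacement_size = displacements,
             p_common = colMeans(matrix(pc, n_sims)))
}

#' Small-displacement slope of localization error
#'
#' Ordinary least-squares slope of the along-axis localization error on
#' displacement size, restricted to the small displacements, per (target,
#' axis, viewing time) cell. A descriptive statistic: under pure
#' segregation it is ~0, under full integration it equals the integration
#' weight of the visual percept.
#'
#' @param dataset A trial dataset containing the small displacements.
#' @param small_set Displacements (deg) included in the regression.
#' @return A data.frame with columns `target`, `displacement_axis`,
#'   `viewing_ms`, `slope`, `n`.
#' @export
small_displacement_slope <- function(dataset,
                                     small_set = c(0, -0.5, 0.5, -1, 1)) {
  d <- dataset[dataset$displacement_size %in% small_set, , drop = FALSE]
  if (length(unique(d$displacement_size)) < 2L)
    stop("need at least 2 distinct small displacements in the dataset")
  d$err_along <- .err_along(d)
  cells <- unique(d[c("target", "displacement_axis", "viewing_ms")])
  rownames(cells) <- NULL
  cells$slope <- NA_real_
  cells$n <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sub <- d[d$target == cells$target[i] &
               d$displacement_axis == cells$displacement_axis[i] &
               d$viewing_ms == cells$viewing_ms[i], , drop = FALSE]
    cells$slope[i] <- unname(coef(lm(err_along ~ displacement_size,
                                     data = sub))[2])
    cells$n[i] <- nrow(sub)
  }
  cells
}

#' Write a curve table to CSV
#' @param curves A `"curve_table"` (or any data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  write.csv(as.data.frame(curves), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot localization-error curves
#'
#' Mean signed error against displacement, one panel per target x axis,
#' colored by viewing duration (requires ggplot2).
#'
#' @param curves Output of [error_curves()].
#' @return A ggplot object.
#' @export
plot_error_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_error_curves requires the 'ggplot2' package")
  ggplot2::ggplot(as.data.frame(curves),
                  ggplot2::aes(x = displacement_size, y = mean_error,
                               color = factor(viewing_ms))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_error - sem,
                                          ymax = mean_error + sem)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(target ~ displacement_axis) +
    ggplot2::labs(x = "displacement (deg)",
                  y = "mean localization error (deg)",
                  color = "viewing (ms)")
}
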