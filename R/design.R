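# Experiment design: target geometry, factorial trial enumeration, pooling
# conventions and the localization-error sign convention.

#' Canonical target layout
#'
#' The three targets form an equilateral triangle with 15 deg sides in a
#' canonical screen frame: the fixation target (FT) at the origin, the
#' saccade target (ST) 15 deg to the right (the saccade direction defines
#' positive x), and the non-foveated target (NT) midway between them,
#' 15·sin(60°) ≈ 12.99 deg above the FT–ST axis. All coordinates are in
#' degrees of visual angle; y is positive upward.
#'
#' @return A list with elements `ft`, `st`, `nt`, each a length-2 numeric
#'   vector `(x, y)` in degrees.
#' @examples
#' target_layout()
#' @export
target_layout <- function() {
  list(ft = c(0, 0),
       st = c(15, 0),
       nt = c(7.5, 15 * sqrt(3) / 2))
}

#' Positions of named targets in the canonical frame
#'
#' @param target Character vector with entries `"ft"`, `"st"` or `"nt"`.
#' @param layout A target layout, by default [target_layout()].
#' @return An `n x 2` matrix of positions in degrees.
#' @export
target_position <- function(target, layout = target_layout()) {
  pos <- rbind(ft = layout$ft, st = layout$st, nt = layout$nt)
  idx <- match(target, rownames(pos))
  if (anyNA(idx))
    stop("unknown target: ", paste(unique(target[is.na(idx)]), collapse = ", "))
  unname(pos[idx, , drop = FALSE])
}

#' Displacement levels of the SSD design (degrees)
#' @return Numeric vector of the 11 displacement sizes.
#' @export
displacement_levels <- function() {
  c(-5, -3, -2, -1, -0.5, 0, 0.5, 1, 2, 3, 5)
}

#' Postsaccadic viewing durations (ms)
#'
#' The "until response" condition is modeled as a third categorical level
#' labeled 1000 ms with its own visual noise parameter.
#' @return Integer vector `c(50, 300, 1000)`.
#' @export
viewing_levels <- function() c(50L, 300L, 1000L)

#' Enumerate the full factorial trial design
#'
#' Every combination of 3 targets, 11 displacement sizes, 2 displacement
#' axes (parallel/orthogonal to the saccade), 3 postsaccadic viewing
#' durations, 2 saccade directions and 2 NT sides: 792 distinct trial types.
#' The two zero-displacement cells (one per axis) are physically identical
#' but kept distinct, which is what yields the 792/198 counts.
#'
#' @return A data.frame with one row per trial type and columns `target`,
#'   `displacement_size`, `displacement_axis`, `viewing_ms`, `saccade_dir`,
#'   `nt_side`.
#' @examples
#' nrow(full_design())  # 792
#' @export
full_design <- function() {
  d <- expand.grid(
    target = c("ft", "st", "nt"),
    displacement_size = displacement_levels(),
    displacement_axis = c("parallel", "orthogonal"),
    viewing_ms = viewing_levels(),
    saccade_dir = c("left", "right"),
    nt_side = c("above", "below"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' Pool trial conditions into the canonical configuration
#'
#' The four screen configurations (left/right saccade, NT above/below) are
#' mirror images of the canonical one (rightward saccade, NT above); their
#' data are pooled by dropping the configuration flags. The full 792-type
#' design pools to 198 distinct conditions.
#'
#' @param conditions A data.frame of trial conditions as returned by
#'   [full_design()] (the configuration columns may already be absent).
#' @return A data.frame of distinct pooled conditions with columns `target`,
#'   `displacement_size`, `displacement_axis`, `viewing_ms`.
#' @export
pool_conditions <- function(conditions) {
  keep <- setdiff(names(conditions), c("saccade_dir", "nt_side"))
  out <- unique(conditions[keep])
  rownames(out) <- NULL
  out
}

#' The 198 pooled SSD conditions
#' @return `pool_conditions(full_design())`.
#' @export
pooled_design <- function() pool_conditions(full_design())

#' Reflect screen points into the canonical configuration
#'
#' Maps points measured under any of the four screen configurations into the
#' canonical frame (rightward saccade, NT above): the horizontal axis is
#' mirrored for leftward saccades and the vertical axis for NT-below
#' configurations. Applying the transform twice with the same flags is the
#' identity.
#'
#' @param point A 2D point or `n x 2` matrix, degrees.
#' @param saccade_dir `"left"` or `"right"` (scalar or length n).
#' @param nt_side `"above"` or `"below"` (scalar or length n).
#' @return An `n x 2` matrix of transformed points.
#' @export
pooling_transform <- function(point, saccade_dir = "right", nt_side = "above") {
  p <- as_xy(point)
  n <- nrow(p)
  saccade_dir <- recycle_to(saccade_dir, n)
  nt_side <- recycle_to(nt_side, n)
  if (!all(saccade_dir %in% c("left", "right")))
    stop("'saccade_dir' must be \"left\" or \"right\"")
  if (!all(nt_side %in% c("above", "below")))
    stop("'nt_side' must be \"above\" or \"below\"")
  p[, 1] <- ifelse(saccade_dir == "left", -p[, 1], p[, 1])
  p[, 2] <- ifelse(nt_side == "below", -p[, 2], p[, 2])
  p
}

#' Signed localization error
#'
#' Error of a localization response relative to the presaccadic target
#' position, in the canonical frame: positive x is the horizontal saccade
#' direction, positive y is upward.
#'
#' @param response,presaccadic_pos 2D points or `n x 2` matrices, degrees,
#'   canonical frame.
#' @return `response - presaccadic_pos`, an `n x 2` matrix of errors (deg).
#' @export
localization_error <- function(response, presaccadic_pos) {
  r <- as_xy(response)
  p <- as_xy(presaccadic_pos)
  if (nrow(p) == 1L && nrow(r) > 1L) p <- p[rep(1L, nrow(r)), , drop = FALSE]
  if (nrow(r) != nrow(p))
    stop("'response' and 'presaccadic_pos' must have matching rows")
  r - p
}

#' Write a trial design to CSV
#'
#' @param design A design data.frame ([full_design()] or [pooled_design()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
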