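# The 15 free parameters of the mixture model and their serialization.

# Canonical parameter order used everywhere (vectors, optimizer, files).
.param_names <- c(
  "sigma_mx_ft", "sigma_mx_st", "sigma_mx_nt",
  "sigma_my_ft", "sigma_my_st", "sigma_my_nt",
  "sigma_v_50", "sigma_v_300", "sigma_v_1000",
  "sigma_f", "sigma_pi_x", "sigma_pi_y",
  "pi_x", "pi_y", "p_c")

#' Model parameters of the causal-inference mixture model
#'
#' The model has exactly 15 free parameters, all in degrees except the
#' common-cause prior probability:
#' \describe{
#'   \item{`sigma_mx_*`, `sigma_my_*`}{SD of the remapped memory percept `m`
#'     per target (ft/st/nt), separately parallel (x) and orthogonal (y) to
#'     the saccade.}
#'   \item{`sigma_v_50/300/1000`}{Isotropic SD of the postsaccadic visual
#'     percept `v`, one per viewing duration.}
#'   \item{`sigma_f`}{Width of the isotropic foveal prior that pulls `m`
#'     toward the fixation target and `v` toward the saccade landing point.}
#'   \item{`sigma_pi_x`, `sigma_pi_y`}{Widths of the anisotropic allocentric
#'     prior over target positions.}
#'   \item{`pi_x`, `pi_y`}{Center of the allocentric prior, expressed
#'     relative to the fixation target (which is the canonical-frame
#'     origin).}
#'   \item{`p_c`}{Prior probability that pre- and postsaccadic percepts share
#'     a common cause (the target did not move).}
#' }
#'
#' @param ... The 15 named scalar parameters (see names above).
#' @return A named numeric vector of class `"model_params"`.
#' @examples
#' p <- observer_params(1)
#' p["p_c"]
#' @export
model_params <- function(...) {
  as_model_params(c(...))
}

#' Coerce to model parameters
#'
#' @param x A named numeric vector, named list, or one-row data.frame
#'   containing all 15 parameters.
#' @return A validated `"model_params"` vector in canonical order.
#' @export
as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(validate_params(x))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected exactly one parameter row")
    x <- unlist(x[intersect(names(x), .param_names)])
  }
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) stop("parameters must be named")
  missing <- setdiff(.param_names, names(x))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  p <- as.numeric(x[.param_names])
  names(p) <- .param_names
  class(p) <- "model_params"
  validate_params(p)
}

#' Validate model parameters
#'
#' Checks that all 15 parameters are present and finite, that every sigma is
#' strictly positive and that `p_c` lies in `[0, 1]`.
#'
#' @param params A `"model_params"` vector.
#' @return `params`, invisibly validated (errors otherwise).
#' @export
validate_params <- function(params) {
  if (length(params) != 15L || !all(names(params) == .param_names))
    stop("model parameters must be the 15 canonical named values")
  if (!all(is.finite(params))) stop("model parameters must be finite")
  sig <- params[grep("^sigma_", .param_names)]
  if (any(sig <= 0)) stop("all sigma parameters must be strictly positive")
  if (params["p_c"] < 0 || params["p_c"] > 1)
    stop("'p_c' must lie in [0, 1]")
  invisible(params)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Causal-inference model parameters (deg; p_c a probability):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

# Memory-percept SDs for given targets: n x 2 matrix (x, y).
.sigma_m <- function(params, target) {
  cbind(unname(params[paste0("sigma_mx_", target)]),
        unname(params[paste0("sigma_my_", target)]))
}

# Visual-percept SD for given viewing durations.
.sigma_v <- function(params, viewing_ms) {
  unname(params[paste0("sigma_v_", as.integer(viewing_ms))])
}

# Allocentric prior center in the canonical frame (FT at the origin).
.pi_pos <- function(params) unname(params[c("pi_x", "pi_y")])

#' Read / write model parameters
#'
#' Parameters are stored as a flat key-value mapping with the 15 canonical
#' keys; the format follows the file extension (`.yaml`/`.yml` or `.json`).
#' Values round-trip losslessly.
#'
#' @param params A `"model_params"` vector.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `"model_params"` vector.
#' @export
write_params <- function(params, path) {
  params <- as_model_params(params)
  vals <- as.list(setNames(unclass(params), names(params)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported parameter file extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unsupported parameter file extension: ", ext)
  as_model_params(vals)
}

#' Reference observer parameter sets
#'
#' Best-fit parameter values for eleven observers in an SSD localization
#' task, shipped with the package as simulation ground truth. Row 1 is the
#' default generative parameter set used throughout the examples and the
#' parameter-recovery analyses.
#'
#' @param observer Optional observer number (1--11). If given, that row is
#'   returned as a `"model_params"` vector; otherwise the full table.
#' @return A data.frame (`observer` + the 15 parameters) or a
#'   `"model_params"` vector.
#' @examples
#' mean(observer_params()$p_c)
#' observer_params(1)
#' @export
observer_params <- function(observer = NULL) {
  path <- system.file("extdata", "observer_params.csv", package = "saccadeCI",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(observer)) return(tab)
  if (!observer %in% tab$observer) stop("unknown observer: ", observer)
  as_model_params(tab[tab$observer == observer, ])
}
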