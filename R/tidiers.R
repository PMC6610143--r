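#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per parameter, `glance()`
#' a one-row model summary.
#'
#' @param x a `diffusion_fit`, `frap_fit`, `binding_fit` or
#'   `registration_transform`.
#' @param ... unused.
#' @return a tibble.
#' @name spottrackr-tidiers
NULL

#' @rdname spottrackr-tidiers
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept", "D"),
    estimate = c(x$m, x$intercept, x$D),
    conf_half_width_95 = c(x$ci95 * 4, NA_real_, x$ci95)
  )
}

#' @rdname spottrackr-tidiers
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D_um2_s = x$D, ci95_um2_s = x$ci95, slope_um2_s = x$m,
         intercept_um2 = x$intercept, n_points_fit = x$n_points_fit,
         negative_slope = x$negative_slope)
}

#' @rdname spottrackr-tidiers
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("k", "t_half", "mobile_fraction", "plateau", "I0"),
    estimate = c(x$k, x$t_half, x$mobile_fraction, x$plateau, x$I0)
  )
}

#' @rdname spottrackr-tidiers
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(k_per_s = x$k, t_half_s = x$t_half,
         mobile_fraction = x$mobile_fraction, plateau = x$plateau,
         model = x$model, converged = x$converged)
}

#' @rdname spottrackr-tidiers
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("k_on", "k_off", "K_D", "R_max"),
    estimate = c(x$k_on, x$k_off, x$K_D, x$R_max),
    std_error = c(unname(x$se["k_on"]), unname(x$se["k_off"]),
                  NA_real_, unname(x$se["R_max"]))
  )
}

#' @rdname spottrackr-tidiers
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(k_on_per_M_s = x$k_on, k_off_per_s = x$k_off, K_D_M = x$K_D,
         K_D_nM = x$K_D * 1e9, R_max = x$R_max, rmse = x$rmse,
         n_curves = x$n_curves, converged = x$converged)
}

#' @rdname spottrackr-tidiers
#' @method tidy registration_transform
#' @export
tidy.registration_transform <- function(x, ...) {
  tibble(
    term = c("a11", "a12", "a21", "a22", "dx", "dy"),
    estimate = c(x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2],
                 x$offset[1], x$offset[2])
  )
}

#' @rdname spottrackr-tidiers
#' @method glance registration_transform
#' @export
glance.registration_transform <- function(x, ...) {
  tibble(model = x$model, rmse_px = x$rmse_px, n_pairs = x$n_pairs)
}
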