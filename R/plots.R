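#' Plot an ensemble MSD curve with error bars
#'
#' @param object an `msd_curve` from [ensemble_msd()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$msd_um2 - .data$sem_um2,
                                        ymax = .data$msd_um2 + .data$sem_um2),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_classic()
}

#' Spatial mobility map figure
#'
#' One point per track at its mean position, coloured by its mean
#' frame-to-frame jump size on a continuous scale.
#'
#' @param map a `mobility_map` (or the output of [track_jump_stats()]).
#' @return a ggplot.
#' @export
plot_mobility_map <- function(map) {
  ggplot2::ggplot(as_tibble(map),
                  ggplot2::aes(x = .data$mean_x_um, y = .data$mean_y_um,
                               colour = .data$mean_jump_um)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "mean jump (µm)") +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +       # image convention: y down
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_classic()
}

#' @rdname plot_mobility_map
#' @param object,... autoplot dispatch arguments.
#' @method autoplot mobility_map
#' @export
autoplot.mobility_map <- function(object, ...) plot_mobility_map(object)

#' Plot a normalized FRAP curve, optionally with its fitted recovery
#'
#' @param curve output of [normalize_frap()].
#' @param fit optional `frap_fit` overlaying the fitted model.
#' @return a ggplot.
#' @export
plot_frap <- function(curve, fit = NULL) {
  df <- as_tibble(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_post_s, y = .data$normalized)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity") +
    ggplot2::theme_classic()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    tt <- seq(0, max(df$t_post_s), length.out = 200)
    yy <- fit$I0 + (fit$plateau - fit$I0) * (1 - exp(-fit$k * tt))
    p <- p + ggplot2::geom_line(data = tibble(t_post_s = tt, normalized = yy),
                                colour = "red")
  }
  p
}

#' Plot sensorgrams, optionally with the fitted one-to-one binding model
#'
#' @param sensorgrams tibble or list of tibbles from [make_sensorgram()].
#' @param fit optional `binding_fit`.
#' @return a ggplot.
#' @export
plot_sensorgram <- function(sensorgrams, fit = NULL) {
  if (!is.data.frame(sensorgrams)) sensorgrams <- bind_rows(sensorgrams)
  df <- mutate(sensorgrams, conc_nM = factor(round(.data$concentration_M * 1e9, 3)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$response,
                                        colour = .data$conc_nM)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "response (RU)", colour = "conc (nM)") +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    pred <- df %>%
      group_by(.data$conc_nM) %>%
      group_modify(function(d, g) {
        ta <- max(d$time_s[d$phase == "association"])
        tibble(time_s = d$time_s,
               response = sensorgram_model(d$time_s, fit$k_on, fit$k_off,
                                           fit$R_max, d$concentration_M[1], ta))
      }) %>% ungroup()
    p <- p + ggplot2::geom_line(data = pred, colour = "black",
                                ggplot2::aes(group = .data$conc_nM))
  }
  p
}

#' Plot a normalized run-off curve per channel
#'
#' @param curve output of [runoff_curve()].
#' @param drug_time_s optional drug-addition time drawn as a vertical line.
#' @return a ggplot.
#' @export
plot_runoff <- function(curve, drug_time_s = NULL) {
  df <- mutate(as_tibble(curve), channel = factor(.data$channel))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$mean_norm,
                                        colour = .data$channel)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_norm - .data$sem_norm,
                                        ymax = .data$mean_norm + .data$sem_norm),
                           width = 0) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "spots (normalized to pre-drug)") +
    ggplot2::theme_classic()
  if (!is.null(drug_time_s)) {
    p <- p + ggplot2::geom_vline(xintercept = drug_time_s, linetype = 2)
  }
  p
}
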