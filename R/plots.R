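## ggplot2 views of the result types.

#' Plot a per-system flexibility profile
#'
#' Per-position tracks of RMSF and Neq with region annotation.
#'
#' @param object A [system_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.system_profile <- function(object, ...) {
  df <- object$flex |>
    tidyr::pivot_longer(cols = c("rmsf", "neq"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          rmsf = "RMSF (Å)",
                                          neq = "Neq"))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$value,
                                   colour = .data$region)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (author numbering)", y = NULL,
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a two-system comparison
#'
#' Per-position tracks of Delta-PB, Delta-Neq and Delta-RMSF.
#'
#' @param object A `pb_comparison` from [compare_systems()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_comparison <- function(object, ...) {
  labs <- attr(object, "labels")
  df <- object |>
    tibble::as_tibble() |>
    dplyr::select("position", "region", "delta_pb", "delta_neq", "delta_rmsf") |>
    tidyr::pivot_longer(cols = dplyr::starts_with("delta"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          delta_pb = "ΔPB",
                                          delta_neq = "ΔNeq",
                                          delta_rmsf = "ΔRMSF (Å)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$value,
                                   colour = .data$region)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (author numbering)", y = NULL,
                  title = if (!is.null(labs))
                    sprintf("%s vs %s", labs[1], labs[2])) +
    ggplot2::theme_minimal()
}

#' Plot a PB frequency profile as a position-by-block heat map
#'
#' A frequency-matrix view of per-position Protein Block usage (the
#' same matrix that [logo_matrix()] exports for logo renderers).
#'
#' @param object A `pb_profile` from [pb_frequency_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_profile <- function(object, ...) {
  df <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(cols = dplyr::all_of(pb_labels()),
                        names_to = "pb", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$pb,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "position (author numbering)", y = "Protein Block") +
    ggplot2::theme_minimal()
}
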