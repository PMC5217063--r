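PATTERN_LABELS <- c("oscillation", "rotation", "traveling_wave")

#' Tabulate the geometric phase diagram
#'
#' Aggregates per-chamber classifications into one tile per designed
#' `(W, L)` geometry: per-label counts, the number of classified
#' chambers, and the strict-plurality majority label. Tiles with fewer
#' than `min_n` classified chambers are marked `"insufficient"` (at
#' least 4 chambers of a geometry are required before calling a
#' majority); exact plurality ties are reported as `"tie"`, never
#' silently resolved. Unclassified chambers are tallied separately and
#' do not vote.
#'
#' @param rows tibble with columns `W_um`, `L_um`, `label`.
#' @param min_n minimum classified chambers per tile.
#' @return A tibble with one row per `(W_um, L_um)`: counts per label,
#'   `n`, `n_unclassified`, `majority`.
#' @export
tabulate_phase_diagram <- function(rows, min_n = 4L) {
  stopifnot(nrow(rows) > 0, all(c("W_um", "L_um", "label") %in% names(rows)))
  bad <- setdiff(unique(rows$label), c(PATTERN_LABELS, "unclassified"))
  if (length(bad) > 0) stop("unknown labels: ", paste(bad, collapse = ", "))
  rows |>
    dplyr::count(.data$W_um, .data$L_um, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (l in c(PATTERN_LABELS, "unclassified"))
        if (!l %in% names(d)) d[[l]] <- 0L
      d
    })() |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = sum(dplyr::c_across(dplyr::all_of(PATTERN_LABELS))),
      n_unclassified = .data$unclassified,
      majority = {
        cnt <- dplyr::c_across(dplyr::all_of(PATTERN_LABELS))
        if (.data$n < min_n) "insufficient"
        else {
          top <- which(cnt == max(cnt))
          if (length(top) > 1) "tie" else PATTERN_LABELS[top]
        }
      }) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::any_of("unclassified")) |>
    dplyr::arrange(.data$W_um, .data$L_um)
}

#' Geometry-selection histograms
#'
#' Fraction of each pattern class as a function of one geometric axis of
#' the chambers: designed width, designed length, aspect ratio `L / W`
#' (rounded to 0.1), or area `L * W`. Fractions are over classified
#' chambers only; each group's `n` and unclassified tally are attached.
#'
#' @param rows tibble with columns `W_um`, `L_um`, `label`.
#' @param axis `"width"`, `"length"`, `"aspect_ratio"` or `"area"`.
#' @return A tibble with `axis_value`, one fraction column per label,
#'   `n`, `n_unclassified`.
#' @export
selection_histograms <- function(rows, axis = c("width", "length",
                                                "aspect_ratio", "area")) {
  axis <- match.arg(axis)
  val <- switch(axis,
                width = rows$W_um,
                length = rows$L_um,
                aspect_ratio = round(rows$L_um / rows$W_um, 1),
                area = rows$W_um * rows$L_um)
  d <- dplyr::mutate(rows, axis_value = val)
  d |>
    dplyr::group_by(.data$axis_value) |>
    dplyr::summarise(
      n = sum(.data$label %in% PATTERN_LABELS),
      n_unclassified = sum(.data$label == "unclassified"),
      oscillation = sum(.data$label == "oscillation"),
      rotation = sum(.data$label == "rotation"),
      traveling_wave = sum(.data$label == "traveling_wave"),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(PATTERN_LABELS),
                                ~ .x / pmax(.data$n, 1L))) |>
    dplyr::arrange(.data$axis_value)
}

pattern_palette <- function() {
  c(oscillation = "#4575b4", rotation = "#d73027",
    traveling_wave = "#1a9850", tie = "grey60", insufficient = "grey90")
}

#' Plot a phase diagram as a tile map
#'
#' @param diagram output of [tabulate_phase_diagram()].
#' @return A ggplot object: one coloured tile per designed geometry.
#' @export
plot_phase_diagram <- function(diagram) {
  ggplot2::ggplot(diagram,
                  ggplot2::aes(x = .data$L_um, y = .data$W_um,
                               fill = .data$majority)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.6) +
    ggplot2::scale_fill_manual(values = pattern_palette(), drop = FALSE) +
    ggplot2::labs(x = "chamber length L (µm)",
                  y = "chamber width W (µm)",
                  fill = "majority pattern") +
    ggplot2::theme_minimal()
}

#' Plot a geometry-selection histogram
#'
#' @param hist output of [selection_histograms()].
#' @param axis_label x-axis label.
#' @return A ggplot stacked-bar chart of per-bin label fractions.
#' @export
plot_selection_histogram <- function(hist, axis_label = "geometry") {
  long <- tidyr::pivot_longer(hist, dplyr::all_of(PATTERN_LABELS),
                              names_to = "label", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$axis_value),
                                     y = .data$fraction, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = hist, inherit.aes = FALSE,
      ggplot2::aes(x = factor(.data$axis_value), y = 1.03,
                   label = .data$n), size = 3) +
    ggplot2::scale_fill_manual(values = pattern_palette()) +
    ggplot2::labs(x = axis_label, y = "fraction of chambers",
                  fill = "pattern") +
    ggplot2::theme_minimal()
}
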