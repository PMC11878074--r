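#' Plot the distribution of stiffness parameters
#'
#' Histograms of the five per-taxon stiffness parameters, one facet per
#' parameter (free x scales: force and stiffness scale live near zero while
#' displacement can span orders of magnitude).
#'
#' @param object An `sna_profile`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sna_profile
#' @export
autoplot.sna_profile <- function(object, bins = 30, ...) {
  dat <- tidy(object) |> filter(!is.na(.data$value))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "value", y = "taxa",
                  title = "Per-taxon stiffness parameters")
}

#' Plot real stiffness values against their permutation nulls
#'
#' For each tested parameter, the real per-taxon value is drawn over the
#' central 95% band of its permutation null; taxa classified as
#' significantly increased or decreased are coloured.
#'
#' @param object An `sna_permtest`.
#' @param parameter Parameter(s) to show; default all three tested.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sna_permtest
#' @export
autoplot.sna_permtest <- function(object,
                                  parameter = c("stiffness_scale",
                                                "impact", "stability"),
                                  ...) {
  parameter <- match.arg(parameter, several.ok = TRUE)
  bands <- purrr::map_dfr(parameter, function(p) {
    q <- t(apply(object$nulls[[p]], 1L, function(v) {
      if (all(is.na(v))) c(NA_real_, NA_real_) else
        quantile(v, c(0.025, 0.975), na.rm = TRUE)
    }))
    tibble(taxon = object$taxa, parameter = p,
           lo = q[, 1L], hi = q[, 2L])
  })
  dat <- object$report |>
    filter(.data$parameter %in% !!parameter) |>
    left_join(bands, by = c("taxon", "parameter")) |>
    mutate(taxon = factor(.data$taxon, levels = object$taxa))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$taxon)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                            colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$real, colour = .data$label),
                        size = 1) +
    ggplot2::scale_colour_manual(values = c(
      sig_increased = "#d1495b", sig_decreased = "#00798c",
      not_sig = "grey30", undefined = "grey80")) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5,
                                           size = 6)) +
    ggplot2::labs(x = NULL, y = "value", colour = NULL,
                  title = "Real stiffness values vs permutation null (95% band)")
}

#' Plot a first-order-neighbour graph
#'
#' Fruchterman-Reingold layout with the conventional styling: increased
#' biomarkers and their neighbours in red tones, decreased in blue, shared
#' neighbours in cyan; positive edges green, negative red.
#'
#' @param object An `sna_fon`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sna_fon
#' @export
autoplot.sna_fon <- function(object, seed = 1, ...) {
  if (!nrow(object$nodes)) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty FON graph"))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(object$edges), directed = FALSE,
    vertices = as.data.frame(object$nodes))
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes |>
    mutate(x = xy[, 1L], y = xy[, 2L])
  edges <- object$edges |>
    left_join(select(nodes, "taxon", xi = "x", yi = "y"),
              by = c(taxon_i = "taxon")) |>
    left_join(select(nodes, "taxon", xj = "x", yj = "y"),
              by = c(taxon_j = "taxon"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xi, y = .data$yi, xend = .data$xj,
                   yend = .data$yj,
                   colour = factor(.data$sign, levels = c(1, -1))),
      linewidth = 0.4) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$role,
                   shape = .data$role),
      size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`1` = "#2e8b57", `-1` = "#c0392b"),
      labels = c(`1` = "positive", `-1` = "negative"), name = "edge") +
    ggplot2::scale_fill_manual(values = c(
      biomarker_inc = "#f4a6b8", biomarker_dec = "#9db8e8",
      nn_inc = "#f4a6b8", nn_dec = "#9db8e8", shared_nn = "#7fd4d4")) +
    ggplot2::scale_shape_manual(values = c(
      biomarker_inc = 21, biomarker_dec = 21,
      nn_inc = 23, nn_dec = 23, shared_nn = 22)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "First-order-neighbour graph of biomarker taxa")
}
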