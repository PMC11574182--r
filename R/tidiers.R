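#' Tidiers for simulation and test objects
#'
#' `tidy()` returns the per-item (or per-cluster) tibble; `glance()` returns
#' a one-row summary.
#'
#' @param x A `dp_simulation`, `uncertainty_sweep`, `cluster_test` or
#'   `recovery_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name cohortpe-tidiers
NULL

#' @rdname cohortpe-tidiers
#' @export
tidy.dp_simulation <- function(x, ...) {
  dplyr::select(x$items, "item_id", "set_id", "condition", "strength",
                "congruency", "univariate_pe", "univariate_sharpened",
                "entropy_link")
}

#' @rdname cohortpe-tidiers
#' @export
glance.dp_simulation <- function(x, ...) {
  co <- x$crossover
  tibble::tibble(
    n_items = nrow(x$items),
    temperature = x$temperature,
    pe_crossover = co$crossover[co$kind == "prediction_error"],
    sharpened_crossover = co$crossover[co$kind == "sharpened"],
    pe_match_strong_minus_weak =
      co$match_strong_minus_weak[co$kind == "prediction_error"]
  )
}

#' @rdname cohortpe-tidiers
#' @export
tidy.uncertainty_sweep <- function(x, ...) x$condition_means

#' @rdname cohortpe-tidiers
#' @export
glance.uncertainty_sweep <- function(x, ...) {
  f <- x$flags
  tibble::tibble(
    n_temperatures = nrow(f),
    any_match_reversal = any(f$match_reversal),
    pe_crossover_at_max_t = f$pe_crossover[which.max(f$temperature)],
    sharpened_crossover_at_max_t = f$sharpened_crossover[which.max(f$temperature)]
  )
}

#' @rdname cohortpe-tidiers
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @rdname cohortpe-tidiers
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm, threshold = x$threshold,
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_
  )
}

#' @rdname cohortpe-tidiers
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x),
    accuracy = mean(x$correct),
    accuracy_pe = mean(x$correct[x$mechanism == "prediction_error"]),
    accuracy_sharpened = mean(x$correct[x$mechanism == "sharpened"])
  )
}

#' Plot per-condition simulation results
#'
#' Bars of condition means with per-item (univariate) or per-pair (pattern
#' distance) points, in the style used to summarise divergence-point
#' simulations.
#'
#' @param object A `dp_simulation`.
#' @param type `"distance"` (within-condition pattern distances, per model
#'   kind) or `"univariate"` (per-item readouts).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dp_simulation <- function(object, type = c("distance", "univariate"),
                                   ...) {
  type <- match.arg(type)
  lev <- condition_levels()
  if (type == "distance") {
    pairs <- dplyr::mutate(object$pairs,
                           condition = factor(.data$condition, levels = lev))
    means <- dplyr::mutate(object$condition_means,
                           condition = factor(.data$condition, levels = lev))
    ggplot2::ggplot(pairs, ggplot2::aes(x = .data$condition,
                                        y = .data$distance)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.25, size = 0.6) +
      ggplot2::geom_col(data = means,
                        ggplot2::aes(y = .data$mean_distance),
                        fill = NA, colour = "black", width = 0.6) +
      ggplot2::facet_wrap(~kind, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "pattern distance") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    items <- tidy(object) |>
      tidyr::pivot_longer(c("univariate_pe", "univariate_sharpened"),
                          names_to = "readout", values_to = "value") |>
      dplyr::mutate(condition = factor(.data$condition, levels = lev))
    ggplot2::ggplot(items, ggplot2::aes(x = .data$condition, y = .data$value)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.7) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                            linewidth = 0.3) +
      ggplot2::facet_wrap(~readout, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "model signal") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }
}

#' Heatmap of a representational dissimilarity matrix
#'
#' @param object An `rdm`.
#' @param mask Optional logical exclusion matrix; excluded pairs are blanked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdm <- function(object, mask = NULL, ...) {
  m <- unclass(object)
  if (!is.null(mask)) m[mask] <- NA
  df <- tibble::as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(df) <- c("item_a", "item_b", "distance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item_a, y = .data$item_b,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0(attr(object, "metric"), "\ndistance")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Pointwise t series of a cluster test with significant clusters shaded
#'
#' @param object A `cluster_test`.
#' @param alpha Clusterwise significance level for shading.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_test <- function(object, alpha = 0.05, ...) {
  xvals <- object$times %||% seq_along(object$t)
  df <- tibble::tibble(x = xvals, t = object$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-object$threshold, object$threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(object$times)) "sample" else "time (ms)",
                  y = "t") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$p_value < alpha, , drop = FALSE]
  if (nrow(sig) > 0) {
    shade <- tibble::tibble(xmin = xvals[sig$start], xmax = xvals[sig$end])
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.2, fill = "steelblue",
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Condition means across the temperature sweep
#'
#' @param object An `uncertainty_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.uncertainty_sweep <- function(object, ...) {
  df <- dplyr::mutate(object$condition_means,
                      condition = factor(.data$condition,
                                         levels = condition_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature,
                                   y = .data$mean_distance,
                                   colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "softmax temperature (high = low uncertainty)",
                  y = "mean within-condition pattern distance") +
    ggplot2::theme_minimal()
}
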