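# Human-readable outputs: the textual search summary, the DOT causality
# graph, diary time plots, and the report bundle written to a directory.

#' Textual summary of a model search
#'
#' A pure formatter: every number comes from the `var_search` bookkeeping and
#' the `granger_summary`. The tested-of-enumerated percentage is printed with
#' one decimal.
#'
#' @param search A `var_search`.
#' @param summary Optional `granger_summary`; computed from `search` when
#'   omitted.
#' @return A single string.
#' @export
render_text <- function(search, summary = NULL) {
  if (is.null(summary) && search$n_valid >= 0 && !is.null(search$models$fit)) {
    summary <- try(summarize_granger(search), silent = TRUE)
    if (inherits(summary, "try-error")) summary <- NULL
  }
  pct <- sprintf("%.1f%%", 100 * search$tested / search$enumerated)
  lines <- c(
    "Automated VAR model search",
    "==========================",
    paste0("Variables: ", paste(search$variables, collapse = ", ")),
    sprintf("%d VAR models out of %d possible combinations were tested (%s).",
            search$tested, search$enumerated, pct),
    sprintf("A total of %d models were not tested due to redundancy.",
            search$skipped_redundant),
    sprintf("Trend variable included: %s",
            if (isTRUE(search$trend)) "yes" else "no"),
    sprintf("Of the models tested, %d were valid (ordering criterion: %s).",
            search$n_valid, search$criterion))

  vm <- valid_models(search)
  if (nrow(vm) > 0) {
    best <- vm[1, ]
    lines <- c(lines, sprintf(
      "Best model: %s | k = %d, AIC = %.2f, BIC = %.2f.",
      best$outliers, best$k, best$AIC, best$BIC))
  }

  if (is.null(summary) || summary$none) {
    lines <- c(lines, "Granger causality summary: none.")
  } else {
    lines <- c(lines, "Granger causality summary:",
               purrr::map_chr(seq_len(nrow(summary$edges)), function(i) {
                 e <- summary$edges[i, ]
                 sprintf("  %s -> %s (%s; %.0f%% of valid models; best-model p = %.3g)",
                         e$cause, e$effect, e$sign_class, 100 * e$proportion,
                         e$best_model_p)
               }))
  }
  paste(lines, collapse = "\n")
}

.edge_styles <- c(positive = "solid", negative = "dashed",
                  mixed_within = "dashdot", mixed_across = "dotted")
.edge_colors <- c(positive = "green", negative = "red",
                  mixed_within = "orange", mixed_across = "gray")

#' Render the Granger summary as a DOT graph
#'
#' One node per variable and one directed edge per Granger association. Edge
#' pen-width is `base + span * proportion` so that thickness is monotone in
#' the share of valid models supporting the edge. Line styles encode the
#' sign: positive solid, negative dashed, mixed-within dash-dot, mixed-across
#' dotted (colors green/red/orange/gray are emitted as well for renderers
#' that prefer them; note that the `dashdot` style token is an extension not
#' all DOT renderers draw). Node and edge ordering is deterministic.
#'
#' @param summary A `granger_summary`.
#' @param base,span Affine pen-width map parameters (defaults 1 and 4).
#' @return The DOT document as a single string.
#' @export
render_graph <- function(summary, base = 1, span = 4) {
  lines <- c("digraph granger {", "  rankdir=LR;",
             "  node [shape=ellipse];")
  lines <- c(lines, sprintf("  \"%s\";", summary$variables))
  if (!summary$none) {
    for (i in seq_len(nrow(summary$edges))) {
      e <- summary$edges[i, ]
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [penwidth=%.2f, style=%s, color=%s, label=\"%.0f%%\"];",
        e$cause, e$effect, base + span * e$proportion,
        .edge_styles[[e$sign_class]], .edge_colors[[e$sign_class]],
        100 * e$proportion))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Time plots of the diary series
#'
#' One plot per selected variable: 1-based day index on the horizontal axis,
#' raw (untransformed) values on the vertical; outlier days of a chosen model
#' can be annotated.
#'
#' @param dataset An `ema_dataset`.
#' @param variables Variables to plot (default: all endogenous).
#' @param outlier_days Optional named list of day indices to mark per
#'   variable.
#' @return Named list of ggplot objects, one per variable.
#' @export
render_time_plots <- function(dataset, variables = NULL, outlier_days = NULL) {
  vars <- variables %||% ema_variables(dataset)
  vals <- ema_values(dataset)
  plots <- purrr::map(vars, function(v) {
    df <- tibble::tibble(day = seq_len(nrow(vals)), value = vals[, v])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value)) +
      ggplot2::geom_line(color = "grey40") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "Day", y = v, title = paste0("Daily ", v)) +
      ggplot2::theme_minimal()
    days <- outlier_days[[v]]
    if (length(days) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = days, linetype = "dotted",
                                   color = "red")
    }
    p
  })
  names(plots) <- vars
  plots
}

#' @describeIn render_time_plots Faceted time plot of all endogenous
#'   variables.
#' @param object An `ema_dataset`.
#' @param ... Unused.
#' @export
autoplot.ema_dataset <- function(object, ...) {
  vals <- ema_values(object)
  df <- tibble::as_tibble(vals) |>
    dplyr::mutate(day = dplyr::row_number()) |>
    tidyr::pivot_longer(-"day", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Granger summary graph
#'
#' Draws the directed network with nodes on a circle; edge width is the
#' proportion of valid models supporting the association, linetype encodes
#' the sign (solid positive, dashed negative, dotdash mixed-within, dotted
#' mixed-across).
#'
#' @param object A `granger_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.granger_summary <- function(object, ...) {
  vars <- object$variables
  ang <- seq(0, 2 * pi, length.out = length(vars) + 1)[seq_along(vars)]
  nodes <- tibble::tibble(variable = vars, x = cos(ang), y = sin(ang))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::theme_void()
  if (!object$none) {
    ed <- dplyr::left_join(object$edges, nodes,
                           by = c("cause" = "variable")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nodes, by = c("effect" = "variable")) |>
      dplyr::mutate(shrink = 0.15,
                    xs = .data$x0 + .data$shrink * (.data$x - .data$x0),
                    ys = .data$y0 + .data$shrink * (.data$y - .data$y0),
                    xe = .data$x - .data$shrink * (.data$x - .data$x0),
                    ye = .data$y - .data$shrink * (.data$y - .data$y0))
    lt <- c(positive = "solid", negative = "dashed",
            mixed_within = "dotdash", mixed_across = "dotted")
    p <- p + ggplot2::geom_curve(
      data = ed,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xe,
                   yend = .data$ye, linewidth = .data$proportion,
                   linetype = .data$sign_class),
      curvature = 0.15, arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt")),
      color = "grey20") +
      ggplot2::scale_linewidth(range = c(0.5, 2.5), limits = c(0, 1),
                               name = "Proportion of valid models") +
      ggplot2::scale_linetype_manual(values = lt, name = "Sign")
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$variable), size = 4)
}

#' Write the full report bundle to a directory
#'
#' Writes `report.txt`, `models.csv`, `models.json`, `granger.json`,
#' `granger.dot`, and (when an SVG device is available)
#' `timeplot_<variable>.svg` per selected variable.
#'
#' @param search A `var_search`.
#' @param summary Optional `granger_summary` (computed when omitted).
#' @param dataset The analysed `ema_dataset`; defaults to the one stored in
#'   the search.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(search, summary = NULL, dataset = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- summary %||% summarize_granger(search)
  dataset <- dataset %||% search$dataset
  files <- character(0)

  f <- file.path(dir, "report.txt")
  writeLines(render_text(search, summary), f)
  files <- c(files, f)

  f <- file.path(dir, "models.csv")
  readr::write_csv(tidy(search), f, progress = FALSE)
  files <- c(files, f)

  f <- file.path(dir, "models.json")
  jsonlite::write_json(tidy(search), f, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, f)

  f <- file.path(dir, "granger.json")
  jsonlite::write_json(list(edges = summary$edges, n_valid = summary$n_valid,
                            alpha = summary$alpha, none = summary$none),
                       f, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, f)

  f <- file.path(dir, "granger.dot")
  writeLines(render_graph(summary), f)
  files <- c(files, f)

  if (capabilities("cairo")) {
    best_days <- NULL
    vm <- valid_models(search)
    if (nrow(vm) > 0) best_days <- vm$spec[[1]]$outlier_days
    plots <- render_time_plots(dataset, search$variables, best_days)
    for (v in names(plots)) {
      f <- file.path(dir, paste0("timeplot_", v, ".svg"))
      grDevices::svg(f, width = 8, height = 3)
      print(plots[[v]])
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}
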