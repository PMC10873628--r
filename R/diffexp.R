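# Volcano-space classification, selection sets, per-feature replicate
# summaries, and plot-ready volcano figure data.

#' Fold-change and significance cutoffs
#'
#' Cutoffs mark the dotted lines on a volcano plot: vertical lines at
#' +/- `fc_cutoff` (log2 units) and a horizontal line at `sig_cutoff`
#' (-log10 units). The shipped defaults (|log2 FC| > 0.6, -log10 p > 1.301,
#' i.e. ~1.5-fold and p < 0.05) are presets, not a recommendation; set them
#' to the values used in your differential analysis.
#'
#' @param fc_cutoff Non-negative log2 fold-change cutoff.
#' @param sig_cutoff Non-negative -log10 significance cutoff.
#' @return A `cutoff_config`.
#' @export
cutoff_config <- function(fc_cutoff = 0.6, sig_cutoff = 1.301) {
  if (!is.finite(fc_cutoff) || !is.finite(sig_cutoff) ||
      fc_cutoff < 0 || sig_cutoff < 0) {
    vn_config_error("cutoffs must be finite and non-negative")
  }
  structure(list(fc_cutoff = as.numeric(fc_cutoff),
                 sig_cutoff = as.numeric(sig_cutoff)),
            class = "cutoff_config")
}

SIG_CLASSES <- c("NS_NC", "S_NC", "NS_C", "S_C")

#' Classify volcano points into the four significance/change classes
#'
#' A feature is *significant* when its -log10 significance strictly exceeds
#' `sig_cutoff`, and *changed* when |log2 fold change| strictly exceeds
#' `fc_cutoff`; the four combinations partition any table:
#' `NS_NC` (neither), `S_NC` (significant only), `NS_C` (changed only),
#' `S_C` (both — the usual "hit" class). Comparisons are strict, so a point
#' lying exactly on a dotted cutoff line falls in the less-extreme class.
#'
#' @param log2_fc Numeric vector of log2 fold changes.
#' @param neglog10_sig Numeric vector of -log10 significances.
#' @param cutoffs A [cutoff_config()].
#' @return Factor with levels `NS_NC`, `S_NC`, `NS_C`, `S_C`.
#' @export
#' @examples
#' classify(c(2, 0, 1), c(3, 0, 3), cutoff_config(1, 1.301))
classify <- function(log2_fc, neglog10_sig, cutoffs = cutoff_config()) {
  if (!inherits(cutoffs, "cutoff_config")) {
    vn_config_error("cutoffs must be a cutoff_config()")
  }
  sig <- neglog10_sig > cutoffs$sig_cutoff
  chg <- abs(log2_fc) > cutoffs$fc_cutoff
  cls <- ifelse(sig,
                ifelse(chg, "S_C", "S_NC"),
                ifelse(chg, "NS_C", "NS_NC"))
  factor(cls, levels = SIG_CLASSES)
}

#' Plot style options
#'
#' @param palette `"default"` or `"colorblind"` (Okabe-Ito derived) named
#'   class palettes; both map the four significance classes to colors.
#' @param fade_alpha Opacity used for faded, non-selected points.
#' @param point_size,font_size Numeric display parameters.
#' @param x_limits,y_limits Optional axis bounds (length-2 numeric).
#' @return A `style_options` list.
#' @export
style_options <- function(palette = c("default", "colorblind"),
                          fade_alpha = 0.15, point_size = 1.5,
                          font_size = 11, x_limits = NULL, y_limits = NULL) {
  palette <- match.arg(palette)
  palettes <- list(
    default = c(NS_NC = "#d62728", S_NC = "#1f77b4",
                NS_C = "#9467bd", S_C = "#2ca02c"),
    colorblind = c(NS_NC = "#D55E00", S_NC = "#0072B2",
                   NS_C = "#CC79A7", S_C = "#009E73"))
  structure(list(palette = palette, class_colors = palettes[[palette]],
                 fade_alpha = fade_alpha, point_size = point_size,
                 font_size = font_size, x_limits = x_limits,
                 y_limits = y_limits),
            class = "style_options")
}

#' Define a named selection set
#'
#' @param name Set name.
#' @param member_ids Feature ids; order preserved, duplicates removed.
#' @param color Hex color for the overlay.
#' @return A `selection_set`.
#' @export
selection_set <- function(name, member_ids, color = "#000000") {
  structure(list(name = as.character(name),
                 member_ids = unique(as.character(member_ids)),
                 color = as.character(color)),
            class = "selection_set")
}

#' Batch-select features by gene symbol
#'
#' Builds a selection set from a list of gene symbols (a curated pathway,
#' disease, enzyme-family or organelle list). Matching against the table's
#' gene field is case-insensitive and exact, so human and mouse symbol
#' casing (RAB10 vs Rab10) match without substring false positives.
#'
#' @param table A `diff_table`.
#' @param gene_list Character vector of gene symbols.
#' @param name Name of the resulting set.
#' @param color Overlay color.
#' @return A `selection_set`; attribute `unmatched_genes` lists list entries
#'   matching nothing in the table.
#' @export
batch_select <- function(table, gene_list, name, color = "#e6ab02") {
  if (length(gene_list) == 0) vn_config_error("gene_list must be non-empty")
  gene_list <- unique(as.character(gene_list))
  tab_gene <- toupper(as.character(table$gene))
  hits <- toupper(gene_list)
  matched <- tab_gene %in% hits & !is.na(table$gene)
  sel <- selection_set(name, table$primary_id[matched], color)
  attr(sel, "unmatched_genes") <- gene_list[!hits %in% tab_gene]
  sel
}

#' Assemble plot-ready volcano figure data
#'
#' Splits the table into the four base class series, overlays selection
#' sets (overlays duplicate points, they never remove them from the base
#' series), records the dotted cutoff-line positions, and — when `fade` is
#' on — flags non-selected points for faded rendering so selected features
#' stand out.
#'
#' @param table A `diff_table`.
#' @param cutoffs A [cutoff_config()].
#' @param selections List of [selection_set()] objects.
#' @param style A [style_options()].
#' @param fade Fade non-selected base points (only meaningful with
#'   non-empty selections).
#' @return A `volcano_data` list: `points` (the table plus `class` and
#'   `faded` columns), `series` (per-class split), `overlays`, `cutoff_lines`,
#'   `style`, and `missing_selection_ids` report.
#' @export
build_volcano <- function(table, cutoffs = cutoff_config(),
                          selections = list(), style = style_options(),
                          fade = FALSE) {
  if (nrow(table) == 0) vn_data_error("differential table is empty")
  cls <- classify(table$log2_fc, table$neglog10_sig, cutoffs)
  pts <- as.data.frame(table)
  pts$class <- cls

  missing_report <- list()
  overlays <- list()
  selected_ids <- character()
  for (sel in selections) {
    present <- sel$member_ids %in% pts$primary_id
    if (any(!present)) {
      missing_report[[sel$name]] <- sel$member_ids[!present]
    }
    idx <- match(sel$member_ids[present], pts$primary_id)
    overlays[[sel$name]] <- list(
      name = sel$name, color = sel$color,
      points = pts[idx, c("primary_id", "gene", "log2_fc", "neglog10_sig"),
                   drop = FALSE])
    selected_ids <- c(selected_ids, sel$member_ids[present])
  }
  pts$faded <- if (fade && length(selected_ids) > 0) {
    !(pts$primary_id %in% selected_ids)
  } else rep(FALSE, nrow(pts))

  structure(list(
    points = pts,
    series = split(pts, pts$class),
    overlays = overlays,
    cutoff_lines = list(vertical = c(-cutoffs$fc_cutoff, cutoffs$fc_cutoff),
                        horizontal = cutoffs$sig_cutoff),
    cutoffs = cutoffs,
    style = style,
    missing_selection_ids = missing_report),
    class = "volcano_data")
}

#' Render volcano figure data with ggplot2
#'
#' @param x A `volcano_data` object from [build_volcano()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(x) {
  pts <- x$points
  pts$alpha <- ifelse(pts$faded, x$style$fade_alpha, 1)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = log2_fc, y = neglog10_sig)) +
    ggplot2::geom_point(ggplot2::aes(color = class, alpha = alpha),
                        size = x$style$point_size, show.legend = TRUE) +
    ggplot2::scale_color_manual(values = x$style$class_colors, drop = FALSE) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_vline(xintercept = x$cutoff_lines$vertical,
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = x$cutoff_lines$horizontal,
                        linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 significance",
                  color = "class") +
    ggplot2::theme_bw(base_size = x$style$font_size)
  for (ov in x$overlays) {
    if (nrow(ov$points) > 0) {
      p <- p + ggplot2::geom_point(data = ov$points, color = ov$color,
                                   size = x$style$point_size * 1.4)
    }
  }
  if (!is.null(x$style$x_limits)) p <- p + ggplot2::xlim(x$style$x_limits)
  if (!is.null(x$style$y_limits)) p <- p + ggplot2::ylim(x$style$y_limits)
  p
}

#' Export a volcano figure to SVG
#'
#' @param x A `volcano_data` object.
#' @param path Output `.svg` path.
#' @param width,height Figure size in inches.
#' @return The path, invisibly.
#' @export
save_volcano_svg <- function(x, path, width = 7, height = 5) {
  p <- plot_volcano(x)
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Per-condition replicate summary for one feature
#'
#' Returns, per condition, the non-missing replicate intensities together
#' with their mean, sample standard deviation (n - 1 denominator) and
#' standard error of the mean — the numbers behind per-feature bar charts
#' and violin plots. With a single non-missing replicate the SD and SEM are
#' reported as 0 and flagged `insufficient_replicates`, so pilot data still
#' render rather than erroring.
#'
#' @param matrix A `raw_quant` object.
#' @param id Feature id present in the matrix.
#' @return A `feature_summary`: list with `feature_id` and `conditions`,
#'   a data frame (condition, n, mean, sd, sem, insufficient_replicates)
#'   carrying the raw per-condition values in attribute `values`.
#' @export
summarize_feature <- function(matrix, id) {
  i <- match(id, matrix$feature_ids)
  if (is.na(i)) vn_data_error(sprintf("unknown feature id '%s'", id))
  v <- matrix$intensities[i, ]
  conds <- unique(matrix$samples$condition)
  values <- lapply(conds, function(cc) {
    x <- v[matrix$samples$condition == cc]
    x[!is.na(x)]
  })
  names(values) <- conds
  n <- lengths(values)
  mu <- vapply(values, function(x) if (length(x)) mean(x) else NA_real_,
               numeric(1))
  sdv <- vapply(values, function(x) if (length(x) >= 2) stats::sd(x) else 0,
                numeric(1))
  sem <- ifelse(n >= 1, sdv / sqrt(pmax(n, 1)), NA_real_)
  out <- data.frame(condition = conds, n = as.integer(n), mean = mu,
                    sd = sdv, sem = sem,
                    insufficient_replicates = n < 2,
                    stringsAsFactors = FALSE)
  attr(out, "values") <- values
  structure(list(feature_id = id, conditions = out),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("feature_summary for '%s':\n", x$feature_id))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}
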