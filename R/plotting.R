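# TAGC ("blob") plot rendering: GC on x, log10 coverage on y, one pane
# per library plus the combined library, points colored by the taxa
# passing the legend threshold and gray otherwise.  A machine-readable
# legend manifest accompanies every image so legend content is testable
# without parsing pixels.

PLOT_GRAY <- "#999999"

# deterministic palette: evenly spaced hues indexed by descending
# taxon count, so re-renders are stable
legend_palette <- function(k) {
  if (k == 0L) return(character(0))
  hues <- seq(15, 375, length.out = k + 1)[seq_len(k)]
  grDevices::hcl(h = hues, c = 100, l = 65)
}

#' Plot specification for TAGC rendering
#'
#' @param rank rank whose annotation colors the points.
#' @param threshold legend threshold as a fraction of annotated contigs
#'   (default 0.01, i.e. taxa under 1% are hidden and plot gray).
#' @param panes library labels to draw, one pane each; default: every
#'   library in the table (the combined `total` pane last).
#' @param y_floor pseudo-coverage for zero-depth contigs so they stay
#'   visible on the log axis (default 0.01).
#' @param format `"png"` or `"svg"`.
#' @param point_size,alpha point styling.
#' @return A `plot_spec`.
#' @export
plot_spec <- function(rank = "order", threshold = 0.01, panes = NULL,
                      y_floor = 0.01, format = c("png", "svg"),
                      point_size = 1, alpha = 0.6) {
  stopifnot(threshold >= 0, threshold <= 1, y_floor > 0)
  structure(list(rank = rank, threshold = threshold, panes = panes,
                 y_floor = y_floor, format = match.arg(format),
                 point_size = point_size, alpha = alpha),
            class = "plot_spec")
}

resolve_panes <- function(table, spec) {
  libs <- tagc_cov_labels(table)
  panes <- spec$panes
  if (is.null(panes)) {
    panes <- c(setdiff(libs, "total"), intersect("total", libs))
  }
  missing <- setdiff(panes, libs)
  if (length(missing)) {
    format_error("pane librar%s not in table: %s",
                 if (length(missing) > 1) "ies" else "y",
                 paste(missing, collapse = ", "))
  }
  panes
}

legend_manifest <- function(table, spec) {
  taxa <- legend_taxa(table, spec$rank, spec$threshold)
  colors <- legend_palette(length(taxa))
  list(rank = spec$rank,
       threshold = spec$threshold,
       taxa = data.frame(taxon = as.character(taxa),
                         count = as.integer(attr(taxa, "counts")),
                         color = colors,
                         stringsAsFactors = FALSE))
}

write_manifest <- function(manifest, image_path) {
  manifest_path <- paste0(image_path, ".legend.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  manifest_path
}

plot_points <- function(table, spec) {
  panes <- resolve_panes(table, spec)
  manifest <- legend_manifest(table, spec)
  shown <- manifest$taxa$taxon
  taxcol <- table[[paste0("taxlevel_", spec$rank)]]
  display <- ifelse(taxcol %in% shown, taxcol, "other")
  long <- do.call(rbind, lapply(panes, function(lib) {
    data.frame(pane = lib,
               gc = table$gc,
               y = log10(pmax(table[[paste0("cov_", lib)]], spec$y_floor)),
               taxon = display,
               stringsAsFactors = FALSE)
  }))
  long$pane <- factor(long$pane, levels = panes)
  list(long = long, manifest = manifest, panes = panes)
}

#' Render a TAGC plot
#'
#' Draws one pane per library (GC on x, log10 coverage on y) and
#' writes a `<path>.legend.json` manifest listing each legend taxon
#' with its contig count and color.  Zero-coverage contigs are plotted
#' at the `y_floor`, never dropped.  SVG output goes through
#' [export_svg()] (one element per point); PNG through ggplot2.
#'
#' @param table a `tagc_table` with at least one row.
#' @param spec a [plot_spec()].
#' @param path output image path.
#' @return invisibly, list with `path`, `manifest_path`, `manifest`.
#' @export
render_tagc <- function(table, spec = plot_spec(), path) {
  if (!nrow(table)) format_error("cannot render an empty TAGC table")
  if (identical(spec$format, "svg")) {
    return(export_svg(table, spec, path))
  }
  pts <- plot_points(table, spec)
  shown <- pts$manifest$taxa$taxon
  pal <- c(stats::setNames(pts$manifest$taxa$color, shown),
           other = PLOT_GRAY)
  g <- ggplot2::ggplot(pts$long,
                       ggplot2::aes(x = .data$gc, y = .data$y,
                                    colour = .data$taxon)) +
    ggplot2::geom_point(size = spec$point_size, alpha = spec$alpha) +
    ggplot2::scale_colour_manual(values = pal,
                                 breaks = shown,
                                 name = spec$rank) +
    ggplot2::facet_wrap(~pane, nrow = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "GC fraction", y = "log10 read coverage") +
    ggplot2::theme_bw()
  grDevices::png(path, width = 360 * length(pts$panes) + 160, height = 420,
                 res = 96)
  print(g)
  grDevices::dev.off()
  manifest_path <- write_manifest(pts$manifest, path)
  invisible(list(path = path, manifest_path = manifest_path,
                 manifest = pts$manifest))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a TAGC plot as SVG
#'
#' Hand-written SVG with exactly one `<circle class="pt">` element per
#' plotted point per pane, so point counts can be asserted by element
#' tally, and a `<g id="legend">` group only when the legend is
#' non-empty.  The same legend manifest as [render_tagc()] is written
#' alongside.
#'
#' @inheritParams render_tagc
#' @return invisibly, list with `path`, `manifest_path`, `manifest`.
#' @export
export_svg <- function(table, spec = plot_spec(format = "svg"), path) {
  if (!nrow(table)) format_error("cannot render an empty TAGC table")
  pts <- plot_points(table, spec)
  long <- pts$long
  manifest <- pts$manifest
  pal <- c(stats::setNames(manifest$taxa$color, manifest$taxa$taxon),
           other = PLOT_GRAY)

  pane_w <- 320; pane_h <- 300; margin <- 40; legend_w <- 180
  npanes <- length(pts$panes)
  width <- npanes * (pane_w + margin) + margin + legend_w
  height <- pane_h + 2 * margin
  ylim <- range(long$y)
  if (diff(ylim) == 0) ylim <- ylim + c(-0.5, 0.5)
  sx <- function(gc, ipane) {
    margin + (ipane - 1L) * (pane_w + margin) + gc * pane_w
  }
  sy <- function(y) {
    margin + pane_h - (y - ylim[1]) / diff(ylim) * pane_h
  }

  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height))
  for (i in seq_along(pts$panes)) {
    sub <- long[long$pane == pts$panes[i], , drop = FALSE]
    fills <- unname(pal[sub$taxon])
    out <- c(out,
             sprintf('<g class="pane" data-library="%s">',
                     xml_escape(pts$panes[i])),
             sprintf('<rect x="%.1f" y="%.1f" width="%d" height="%d" fill="none" stroke="black"/>',
                     sx(0, i), sy(ylim[2]), pane_w, pane_h),
             sprintf('<text x="%.1f" y="%.1f" font-size="12">%s</text>',
                     sx(0, i), sy(ylim[2]) - 6, xml_escape(pts$panes[i])),
             sprintf('<circle class="pt" cx="%.2f" cy="%.2f" r="2" fill="%s" fill-opacity="%.2f"/>',
                     sx(sub$gc, i), sy(sub$y), fills, spec$alpha),
             "</g>")
  }
  if (nrow(manifest$taxa)) {
    x0 <- npanes * (pane_w + margin) + margin
    rows <- seq_len(nrow(manifest$taxa))
    out <- c(out,
             '<g id="legend">',
             sprintf('<text x="%d" y="%d" font-size="12" font-weight="bold">%s</text>',
                     x0, margin, xml_escape(spec$rank)),
             sprintf('<rect x="%d" y="%d" width="10" height="10" fill="%s"/>',
                     x0, margin + rows * 18, manifest$taxa$color),
             sprintf('<text x="%d" y="%d" font-size="11">%s (%d)</text>',
                     x0 + 14, margin + rows * 18 + 9,
                     xml_escape(manifest$taxa$taxon), manifest$taxa$count),
             "</g>")
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  manifest_path <- write_manifest(manifest, path)
  invisible(list(path = path, manifest_path = manifest_path,
                 manifest = manifest))
}
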