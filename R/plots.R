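# Visualization: pie-chart maps of mixing proportions and admixture-style
# structure plots. Base graphics, equirectangular coordinates, no basemap.

default_palette <- function(K) {
  grDevices::hcl.colors(max(K, 2L), "Dark 3")[seq_len(K)]
}

open_device <- function(out_path, width, height) {
  ext <- tolower(tools::file_ext(out_path))
  switch(ext,
    png = grDevices::png(out_path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(out_path, width = width, height = height),
    stop("unsupported figure format: .", ext)
  )
}

# Wedge polygon for a pie glyph; a full circle when the wedge spans it all.
draw_wedge <- function(x, y, r, frac0, frac1, col, n = 48L) {
  ang <- 2 * pi * seq(frac0, frac1, length.out = max(3L, n))
  xs <- x + r * sin(ang)
  ys <- y + r * cos(ang)
  if (frac1 - frac0 < 1 - 1e-9) {
    xs <- c(x, xs, x)
    ys <- c(y, ys, y)
  }
  graphics::polygon(xs, ys, col = col, border = NA)
}

#' Pie-chart map of mixing proportions
#'
#' Draws one pie glyph per site at its cell-center coordinates, with wedge
#' fractions equal to the site's motif mixing proportions, so the spatial
#' transition between biotas reads as a gradient of mixed colors.
#'
#' @param omega N x K matrix of mixing proportions.
#' @param coords data frame with `site_id`, `lat`, `lon`, one row per site,
#'   in the row order of `omega`.
#' @param out_path output `.png` or `.svg` path.
#' @param palette K colors (default a dark qualitative palette).
#' @param radius glyph radius in degrees.
#' @param main plot title.
#' @return `out_path`, invisibly.
#' @export
plot_pie_map <- function(omega, coords, out_path, palette = NULL,
                         radius = 0.42, main = "Motif mixing") {
  omega <- as.matrix(omega)
  if (nrow(omega) != nrow(coords)) stop("one coordinate pair per site required")
  if (any(is.na(coords$lat)) || any(is.na(coords$lon))) {
    stop("missing coordinates")
  }
  K <- ncol(omega)
  palette <- palette %||% default_palette(K)
  open_device(out_path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(
    NA, xlim = range(coords$lon) + c(-1, 1), ylim = range(coords$lat) + c(-1, 1),
    xlab = "Longitude (deg)", ylab = "Latitude (deg)", main = main, asp = 1
  )
  for (n in seq_len(nrow(omega))) {
    cum <- c(0, cumsum(omega[n, ]))
    for (k in seq_len(K)) {
      if (omega[n, k] > 1e-9) {
        draw_wedge(coords$lon[n], coords$lat[n], radius,
                   cum[k], cum[k + 1L], palette[k])
      }
    }
  }
  graphics::legend("topright", legend = paste0("motif_", seq_len(K)),
                   fill = palette, bty = "n")
  invisible(out_path)
}

#' Admixture-style structure plot
#'
#' One stacked bar per site, segment heights equal to the site's mixing
#' proportions; sites appear in the given order (by default sorted by the
#' first motif's proportion, which orders cells along the biotic gradient).
#'
#' @param omega N x K matrix of mixing proportions.
#' @param out_path output `.png` or `.svg` path.
#' @param site_order permutation of `1..N` (or of site ids when `omega` has
#'   row names).
#' @param palette K colors.
#' @param main plot title.
#' @return `out_path`, invisibly.
#' @export
plot_structure <- function(omega, out_path, site_order = NULL, palette = NULL,
                           main = "Site composition") {
  omega <- as.matrix(omega)
  N <- nrow(omega); K <- ncol(omega)
  if (is.null(site_order)) {
    site_order <- order(omega[, 1L], decreasing = TRUE)
  } else if (is.character(site_order)) {
    site_order <- match(site_order, rownames(omega))
  }
  if (!identical(sort(as.integer(site_order)), seq_len(N))) {
    stop("site_order must be a permutation of the sites")
  }
  palette <- palette %||% default_palette(K)
  open_device(out_path, width = 8, height = 4)
  on.exit(grDevices::dev.off())
  graphics::barplot(
    t(omega[site_order, , drop = FALSE]), col = palette, border = NA,
    space = 0, names.arg = rep("", N), main = main,
    xlab = "Sites (ordered)", ylab = "Mixing proportion"
  )
  graphics::legend("topright", legend = paste0("motif_", seq_len(K)),
                   fill = palette, bty = "n", bg = "white")
  invisible(out_path)
}
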