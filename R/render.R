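# --- scene primitives -------------------------------------------------------
# The renderer first builds a flat display list of rectangles, lines and text
# in figure coordinates (origin top-left, units = points), then hands it to a
# backend: a hand-written SVG emitter (deterministic, byte-stable, used for
# regression testing) or an R graphics device for PDF/PNG.

el_rect <- function(x, y, w, h, fill = NA, stroke = NA, sw = 1, class = NULL)
  list(type = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke, sw = sw, class = class)

el_line <- function(x1, y1, x2, y2, stroke = "#000000", sw = 1)
  list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       stroke = stroke, sw = sw)

el_text <- function(x, y, text, size = 10, fill = "#000000",
                    anchor = "start", bold = FALSE, class = NULL)
  list(type = "text", x = x, y = y, text = text, size = size, fill = fill,
       anchor = anchor, bold = bold, class = class)

gray_hex <- function(g) {
  v <- round(pmax(0, pmin(1, g)) * 255)
  sprintf("#%02x%02x%02x", v, v, v)
}

class_palette <- function(n) {
  pal <- c("#4477aa", "#ee6677", "#228833", "#ccbb44", "#66ccee",
           "#aa3377", "#bbbbbb", "#222255")
  rep(pal, length.out = n)
}

# --- layout geometry --------------------------------------------------------

model_geometry <- function(model) {
  p <- model$params
  title_h <- 24
  panel_h <- if (model$panel_kind == "none") 34 else p$panel_height
  block_h <- title_h + panel_h + p$cloud_height + 12
  list(W = p$block_width, title_h = title_h, panel_h = panel_h,
       cloud_h = p$cloud_height, block_h = block_h,
       H = block_h * length(model$blocks))
}

#' Figure height of a summary model
#'
#' Total figure height in points; exactly linear in the number of blocks.
#'
#' @param model a [summary_model()].
#' @return `c(width, height)` in points.
#' @export
model_dimensions <- function(model) {
  g <- model_geometry(model)
  c(width = g$W, height = g$H)
}

# --- scene assembly ---------------------------------------------------------

build_scene <- function(model) {
  g <- model_geometry(model)
  p <- model$params

  # grays are a figure-wide channel: pool every cloud's weights first
  all_items <- lapply(model$blocks, function(b)
    lapply(b$clouds, function(cl) {
      if (is.null(cl) || nrow(cl) == 0)
        return(data.frame(text = character(0), weight = numeric(0)))
      it <- compute_weights(cl, cap = p$weight_cap)
      it[it$weight > 0, , drop = FALSE]
    }))
  weights <- lapply(all_items, function(bl) lapply(bl, function(it) it$weight))
  grays <- compute_grays(weights, gray_range = p$gray_range)

  els <- list(el_rect(0, 0, g$W, g$H, fill = "#ffffff"))
  add <- function(e) els[[length(els) + 1L]] <<- e

  for (bi in seq_along(model$blocks)) {
    b <- model$blocks[[bi]]
    y0 <- (bi - 1) * g$block_h
    add(el_text(10, y0 + 17, b$title, size = 13, bold = TRUE,
                class = "block-title"))
    add(el_line(0, y0 + g$block_h, g$W, y0 + g$block_h, stroke = "#dddddd"))

    panel_box <- c(x = 60, y = y0 + g$title_h + 4,
                   w = g$W - 60 - 170, h = g$panel_h - 8)
    if (b$panel$kind == "boxplot") {
      els <- c(els, draw_boxplot_panel(b$panel, panel_box))
    } else if (b$panel$kind == "histogram") {
      els <- c(els, draw_histogram_panel(b$panel, panel_box))
    }
    # gene counts sit next to the panel
    for (ai in seq_along(b$annotation))
      add(el_text(g$W - 160, panel_box["y"] + 12 + 14 * (ai - 1),
                  b$annotation[ai], size = 10, fill = "#333333",
                  class = "panel-annotation"))
    if (!is.null(b$panel$note))
      add(el_text(g$W - 160, panel_box["y"] + 12 + 14 * length(b$annotation),
                  b$panel$note, size = 10, fill = "#333333",
                  class = "panel-note"))

    cloud_y <- y0 + g$title_h + g$panel_h + 4
    n_clouds <- length(b$gene_lists)
    for (ci in seq_len(n_clouds)) {
      if (n_clouds == 1) {
        cv <- c(x = 20, y = cloud_y, w = g$W - 40, h = g$cloud_h - 8)
      } else if (ci == 1) {   # negative / down cloud on the left
        cv <- c(x = 10, y = cloud_y, w = g$W / 2 - 20, h = g$cloud_h - 8)
      } else {                # positive / up on the right
        cv <- c(x = g$W / 2 + 10, y = cloud_y, w = g$W / 2 - 20,
                h = g$cloud_h - 8)
      }
      items <- all_items[[bi]][[ci]]
      if (nrow(items) == 0) {
        add(el_text(cv["x"] + cv["w"] / 2, cv["y"] + cv["h"] / 2, "0 terms",
                    size = 10, fill = "#999999", anchor = "middle",
                    class = "empty-cloud"))
        next
      }
      items$gray <- grays[[bi]][[ci]]
      lay <- place_words(items, canvas = unname(cv[c("w", "h")]),
                         max_font = p$max_font, min_font = p$min_font)
      for (wi in seq_len(nrow(lay$words))) {
        wrow <- lay$words[wi, ]
        add(el_text(cv["x"] + wrow$x, cv["y"] + wrow$y + 0.85 * wrow$h,
                    wrow$text, size = wrow$size,
                    fill = gray_hex(wrow$gray), class = "cloud-word"))
      }
    }
    if (n_clouds == 2)
      add(el_line(g$W / 2, cloud_y, g$W / 2, cloud_y + g$cloud_h - 8,
                  stroke = "#eeeeee"))
  }
  list(W = g$W, H = g$H, elements = els)
}

draw_boxplot_panel <- function(panel, box) {
  st <- panel$stats
  m <- nrow(st)
  rng <- range(st$ymin, st$ymax)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  ymap <- function(v)
    box["y"] + box["h"] - (v - rng[1]) / (rng[2] - rng[1]) * box["h"]
  slot <- box["w"] / m
  bw <- 0.6 * slot
  els <- list(el_rect(box["x"], box["y"], box["w"], box["h"],
                      stroke = "#bbbbbb"))
  for (i in seq_len(m)) {
    cx <- box["x"] + (i - 0.5) * slot
    r <- st[i, ]
    els <- c(els, list(
      el_line(cx, ymap(r$ymin), cx, ymap(r$lower), stroke = "#555555"),
      el_line(cx, ymap(r$upper), cx, ymap(r$ymax), stroke = "#555555"),
      el_rect(cx - bw / 2, ymap(r$upper), bw, ymap(r$lower) - ymap(r$upper),
              fill = "#c6dbef", stroke = "#555555"),
      el_line(cx - bw / 2, ymap(r$middle), cx + bw / 2, ymap(r$middle),
              stroke = "#000000", sw = 1.5)))
  }
  els
}

draw_histogram_panel <- function(panel, box) {
  counts <- panel$counts
  breaks <- panel$breaks
  nb <- length(breaks) - 1
  tot <- colSums(counts)
  ymax <- max(tot, 1)
  cols <- class_palette(nrow(counts))
  slot <- box["w"] / nb
  els <- list(el_rect(box["x"], box["y"], box["w"], box["h"],
                      stroke = "#bbbbbb"))
  for (j in seq_len(nb)) {
    ybase <- box["y"] + box["h"]
    for (cl in seq_len(nrow(counts))) {
      cnt <- counts[cl, j]
      if (cnt == 0) next
      hgt <- cnt / ymax * (box["h"] - 2)
      els <- c(els, list(el_rect(box["x"] + (j - 1) * slot + 1,
                                 ybase - hgt, slot - 2, hgt,
                                 fill = cols[cl])))
      ybase <- ybase - hgt
    }
  }
  # class legend along the top edge of the panel
  lx <- box["x"] + 4
  for (cl in seq_len(nrow(counts))) {
    els <- c(els, list(
      el_rect(lx, box["y"] - 2, 8, 8, fill = cols[cl]),
      el_text(lx + 11, box["y"] + 5, rownames(counts)[cl], size = 8,
              fill = "#333333", class = "legend-label")))
    lx <- lx + 11 + 5.5 * nchar(rownames(counts)[cl]) + 8
  }
  els
}

# --- backends ---------------------------------------------------------------

fmt_num <- function(v) {
  s <- sprintf("%.3f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

scene_to_svg <- function(scene) {
  out <- c(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
    'viewBox="0 0 %s %s" font-family="Helvetica, sans-serif">'),
    fmt_num(scene$W), fmt_num(scene$H), fmt_num(scene$W), fmt_num(scene$H)))
  for (e in scene$elements) {
    out <- c(out, switch(
      e$type,
      rect = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
                     fmt_num(e$x), fmt_num(e$y), fmt_num(e$w), fmt_num(e$h),
                     if (is.na(e$fill)) "none" else e$fill,
                     if (is.na(e$stroke)) "none" else e$stroke,
                     fmt_num(e$sw)),
      line = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                     fmt_num(e$x1), fmt_num(e$y1), fmt_num(e$x2),
                     fmt_num(e$y2), e$stroke, fmt_num(e$sw)),
      text = sprintf('<text%s x="%s" y="%s" font-size="%s" fill="%s"%s%s>%s</text>',
                     if (is.null(e$class)) ""
                     else sprintf(' class="%s"', e$class),
                     fmt_num(e$x), fmt_num(e$y), fmt_num(e$size), e$fill,
                     if (e$anchor == "start") ""
                     else sprintf(' text-anchor="%s"', e$anchor),
                     if (e$bold) ' font-weight="bold"' else "",
                     xml_escape(e$text))))
  }
  c(out, "</svg>")
}

scene_to_device <- function(scene) {
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i", ps = 12)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, scene$W), ylim = c(scene$H, 0))
  for (e in scene$elements) {
    if (e$type == "rect") {
      graphics::rect(e$x, e$y + e$h, e$x + e$w, e$y,
                     col = if (is.na(e$fill)) NA else e$fill,
                     border = if (is.na(e$stroke)) NA else e$stroke,
                     lwd = e$sw)
    } else if (e$type == "line") {
      graphics::segments(e$x1, e$y1, e$x2, e$y2, col = e$stroke, lwd = e$sw)
    } else if (e$type == "text") {
      adjx <- switch(e$anchor, start = 0, middle = 0.5, end = 1)
      graphics::text(e$x, e$y, labels = e$text, adj = c(adjx, 0),
                     col = e$fill, cex = e$size / 12,
                     font = if (e$bold) 2 else 1)
    }
  }
}

#' Render a summary figure
#'
#' Lays out the model's blocks top to bottom — title strip, data panel with
#' its gene-count annotation, then one or two word clouds (negative/down on
#' the left, positive/up on the right) — and writes the figure. Grayscale
#' levels are computed over the whole figure before any cloud is placed, so
#' equal enrichment strengths look identical across clouds. The SVG backend
#' is byte-deterministic: the same model always produces the same file.
#'
#' @param model a [summary_model()].
#' @param path output file path.
#' @param format `"svg"`, `"pdf"` or `"png"` (default from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
render <- function(model, path, format = c("auto", "svg", "pdf", "png")) {
  stopifnot(inherits(model, "summary_model"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("svg", "pdf", "png"))
      stop("cannot infer format from '", path, "'; pass format explicitly")
  }
  scene <- build_scene(model)
  if (format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(scene_to_svg(scene), con, sep = "\n", useBytes = TRUE)
  } else if (format == "pdf") {
    grDevices::pdf(path, width = scene$W / 72, height = scene$H / 72)
    on.exit(grDevices::dev.off())
    scene_to_device(scene)
  } else {
    grDevices::png(path, width = scene$W, height = scene$H)
    on.exit(grDevices::dev.off())
    scene_to_device(scene)
  }
  invisible(path)
}
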