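#' Word weights from enrichment p-values
#'
#' The display weight of a term is `-log10(p_adj)`, capped at `cap` so a
#' single extreme p-value cannot dominate a cloud. Adjusted p-values of
#' exactly 0 (underflow upstream) are clamped to the smallest positive
#' double, with a warning. Items with `p_adj = 1` carry weight 0 and should
#' be excluded by significance filtering before display.
#'
#' @param terms an `enriched_terms` data frame, or any data frame with
#'   columns `term_name` (or `text`) and `p_adj` (or `p`).
#' @param cap weight ceiling (default 16, i.e. p = 1e-16).
#' @return A data frame of word items: `text`, `weight`.
#' @export
compute_weights <- function(terms, cap = 16) {
  text <- if (!is.null(terms$text)) terms$text else terms$term_name
  p <- if (!is.null(terms$p_adj)) terms$p_adj else terms$p
  stopifnot(!is.null(text), !is.null(p), all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warning("adjusted p-value of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  w <- pmin(-log10(p), cap)
  data.frame(text = as.character(text), weight = w, stringsAsFactors = FALSE)
}

#' Figure-wide grayscale levels
#'
#' Within one cloud, font sizes are rescaled to fill the canvas, so sizes are
#' not comparable across clouds. The absolute strength of enrichment is
#' instead carried by a grayscale channel computed over ALL clouds of a
#' figure at once: a single affine map takes the figure-wide weight range
#' `[w_min, w_max]` to gray levels `[0.65, 0]` (0 = black = strongest).
#' Identical weights therefore get identical grays wherever they appear.
#' The lightest level is 0.65, not 1, so the weakest term stays legible.
#' A degenerate range (all weights equal) maps everything to black.
#'
#' @param weights numeric vector of weights pooled across the figure, or a
#'   list of per-cloud weight vectors.
#' @param gray_range `c(lightest, darkest)` gray levels (default
#'   `c(0.65, 0)`).
#' @return Gray levels in the same shape as `weights`.
#' @export
compute_grays <- function(weights, gray_range = c(0.65, 0)) {
  flat <- unlist(weights, use.names = FALSE)
  if (length(flat) == 0) return(weights)
  wmin <- min(flat); wmax <- max(flat)
  map <- function(w) {
    if (wmax == wmin) return(rep(gray_range[2], length(w)))
    gray_range[1] + (w - wmin) / (wmax - wmin) * (gray_range[2] - gray_range[1])
  }
  if (is.list(weights)) {
    rapply(weights, map, classes = "numeric", how = "replace")
  } else {
    map(weights)
  }
}

#' Pack words into a cloud layout
#'
#' Greedy deterministic rectangle packing tuned for long multi-word phrases
#' (ontology term names are kept whole: never split, never rotated). Words
#' are placed heaviest first; each word's bounding box is estimated from its
#' font size and character count; candidate anchor positions are scanned on
#' an outward rectangular spiral from the canvas centre, and elongated boxes
#' prefer positions in horizontal bands (small vertical offset first), which
#' is what lets long phrases tile compactly. If any word cannot be placed,
#' all font sizes are multiplied by `shrink` and the layout restarts, so the
#' size ratios between words are preserved exactly. The procedure is fully
#' deterministic: identical input yields an identical layout.
#'
#' Font sizes within the cloud are proportional to the weights, scaled so the
#' heaviest word gets `max_font` points before any global shrink.
#'
#' @param items data frame with `text` and `weight` (> 0) columns, e.g. from
#'   [compute_weights()]; an optional `gray` column is carried through.
#' @param canvas `c(width, height)` in abstract units (points).
#' @param max_font target font size of the heaviest word, points.
#' @param min_font minimum legible font size; a single word that cannot fit
#'   the canvas even at this size is a layout error.
#' @param shrink global shrink factor applied on a failed pass.
#' @param aspect estimated glyph width as a fraction of font size.
#' @return An object of class `cloud_layout`: `canvas`, `scale` (the global
#'   shrink applied), and `words`, a data frame with `text`, `x`, `y` (box
#'   top-left), `w`, `h`, `size` (font points), `weight`, `gray`.
#' @export
place_words <- function(items, canvas = c(360, 140), max_font = 20,
                        min_font = 4, shrink = 0.95, aspect = 0.55) {
  stopifnot(nrow(items) >= 1, all(canvas > 0))
  if (any(items$weight <= 0))
    stop("all word weights must be positive; filter non-significant items first")
  items <- items[order(-items$weight, items$text), , drop = FALSE]
  base_size <- max_font * items$weight / max(items$weight)
  gray <- if (!is.null(items$gray)) items$gray else rep(0, nrow(items))

  # a word whose box exceeds the canvas at the minimum font can never be placed
  min_w <- aspect * min_font * nchar(items$text)
  min_h <- 1.1 * min_font
  bad <- which(min_w > canvas[1] | min_h > canvas[2])
  if (length(bad) > 0)
    stop("word cannot fit canvas even at minimum font size: '",
         items$text[bad[1]], "'")

  scale <- 1
  repeat {
    sizes <- base_size * scale
    if (max(sizes) < min_font)
      stop("cannot place ", nrow(items), " words at minimum font size on a ",
           canvas[1], "x", canvas[2], " canvas")
    fit <- try_pack(items$text, sizes, canvas, aspect)
    if (!is.null(fit)) break
    scale <- scale * shrink
  }
  words <- data.frame(text = items$text, x = fit$x, y = fit$y,
                      w = fit$w, h = fit$h, size = sizes,
                      weight = items$weight, gray = gray,
                      stringsAsFactors = FALSE)
  structure(list(canvas = canvas, scale = scale, words = words),
            class = "cloud_layout")
}

# one greedy pass; NULL if some word found no collision-free position
try_pack <- function(text, sizes, canvas, aspect) {
  n <- length(text)
  w <- aspect * sizes * nchar(text)
  h <- 1.1 * sizes
  W <- canvas[1]; H <- canvas[2]
  step <- max(2, min(W, H) / 40)
  gx <- seq(0, W, by = step); gy <- seq(0, H, by = step)
  cand <- expand.grid(cx = gx, cy = gy)
  dx <- cand$cx - W / 2; dy <- cand$cy - H / 2
  ring <- pmax(abs(dx), abs(dy))
  # spiral from centre; horizontal-band preference for elongated boxes
  ord_band <- order(ring, abs(dy), abs(dx), dy, dx, method = "radix")
  ord_radial <- order(ring, dx^2 + dy^2, abs(dy), dy, dx, method = "radix")

  px1 <- px2 <- py1 <- py2 <- numeric(0)
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    ord <- if (w[i] > 2.5 * h[i]) ord_band else ord_radial
    cx <- cand$cx[ord]; cy <- cand$cy[ord]
    x1 <- cx - w[i] / 2; y1 <- cy - h[i] / 2
    x2 <- x1 + w[i]; y2 <- y1 + h[i]
    ok <- x1 >= 0 & y1 >= 0 & x2 <= W & y2 <= H
    if (length(px1) > 0) {
      for (b in seq_along(px1)) {
        idx <- which(ok)
        if (length(idx) == 0) break
        hit <- x1[idx] < px2[b] & px1[b] < x2[idx] &
               y1[idx] < py2[b] & py1[b] < y2[idx]
        ok[idx[hit]] <- FALSE
      }
    }
    j <- which.max(ok)   # first TRUE in spiral order
    if (length(j) == 0 || !ok[j]) return(NULL)
    x[i] <- x1[j]; y[i] <- y1[j]
    px1 <- c(px1, x1[j]); py1 <- c(py1, y1[j])
    px2 <- c(px2, x2[j]); py2 <- c(py2, y2[j])
  }
  list(x = x, y = y, w = w, h = h)
}

#' @export
print.cloud_layout <- function(x, ...) {
  cat("cloud_layout:", nrow(x$words), "words on",
      paste(x$canvas, collapse = " x "), "canvas (scale",
      format(x$scale, digits = 3), ")\n")
  invisible(x)
}
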