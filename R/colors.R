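# Palette-based color recording. Picking from a palette captures both a
# machine-comparable sRGB triple and the human-readable label; free-text
# colors are accepted but marked non-computable (no sRGB), which is
# exactly the reliability gap palettes exist to close.

#' Load color palettes from JSON
#'
#' Schema: `[{"name": text, "colors": [{"label": text, "srgb":
#' [r, g, b]}]}]` with components in 0-255. Labels must be unique within
#' a palette and palette names unique in the file.
#'
#' @param path Palette JSON file; defaults to the packaged palettes
#'   (brown, yellow-brown, yellow-green, green, red).
#' @return A named list of `palette` objects.
#' @export
load_palettes <- function(path = system.file("extdata", "palettes.json",
                                             package = "charrec")) {
  data <- jsonlite::read_json(path)
  pals <- list()
  for (p in data) {
    if (!length(p$colors)) {
      stop_charrec(sprintf("palette '%s' is empty", p$name), class = "validation")
    }
    labels <- vapply(p$colors, function(cc) cc$label, character(1))
    if (anyDuplicated(labels)) {
      stop_charrec(sprintf("palette '%s' has duplicate labels", p$name),
                   class = "validation")
    }
    colors <- lapply(p$colors, function(cc) {
      srgb <- as.integer(unlist(cc$srgb))
      check_srgb(srgb)
      list(label = cc$label, srgb = srgb)
    })
    if (!is.null(pals[[p$name]])) {
      stop_charrec(sprintf("duplicate palette name '%s'", p$name),
                   class = "validation")
    }
    pals[[p$name]] <- structure(list(name = p$name, colors = colors),
                                class = "palette")
  }
  pals
}

check_srgb <- function(x) {
  if (length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255)) {
    stop_charrec(sprintf("invalid sRGB triple: (%s)", paste(x, collapse = ", ")),
                 class = "domain")
  }
  invisible(x)
}

#' Pick a color from a palette by label
#'
#' @param palette A `palette` object.
#' @param label Exact color label.
#' @return A `color_value` with `srgb`, `label` and `source = "palette"`.
#'   Unknown labels raise a not-found error listing the closest labels
#'   (by edit distance) as hints.
#' @export
pick_color <- function(palette, label) {
  for (cc in palette$colors) {
    if (cc$label == label) {
      return(structure(list(srgb = cc$srgb, label = cc$label,
                            source = "palette"), class = "color_value"))
    }
  }
  labels <- vapply(palette$colors, function(cc) cc$label, character(1))
  d <- utils::adist(label, labels)[1L, ]
  nearest <- labels[order(d)][seq_len(min(3L, length(labels)))]
  stop_charrec(sprintf("no color '%s' in palette '%s'; nearest labels: %s",
                       label, palette$name, paste(nearest, collapse = ", ")),
               class = "not_found", data = list(nearest = nearest))
}

#' Record a free-text color name
#'
#' Free-text colors carry no sRGB triple and are therefore not
#' computable for comparison; they are accepted for the out-of-palette
#' cases (e.g. "white", "colorless").
#'
#' @param label Color name.
#' @return A `color_value` with `source = "free_text"` and no `srgb`.
#' @export
free_text_color <- function(label) {
  structure(list(srgb = NULL, label = label, source = "free_text"),
            class = "color_value")
}

#' Distance between two sRGB triples
#'
#' The default metric is Euclidean distance in sRGB space; `"redmean"`
#' (a common perceptual approximation) is selectable. Symmetric, zero
#' iff equal.
#'
#' @param a,b Integer sRGB triples in 0-255.
#' @param metric `"euclidean"` (default) or `"redmean"`.
#' @return Non-negative distance.
#' @export
color_distance <- function(a, b, metric = c("euclidean", "redmean")) {
  metric <- match.arg(metric)
  check_srgb(a); check_srgb(b)
  d <- as.numeric(a) - as.numeric(b)
  if (metric == "euclidean") {
    sqrt(sum(d^2))
  } else {
    rbar <- (a[[1L]] + b[[1L]]) / 2
    sqrt((2 + rbar / 256) * d[[1L]]^2 + 4 * d[[2L]]^2 +
           (2 + (255 - rbar) / 256) * d[[3L]]^2)
  }
}

#' Nearest palette color to an arbitrary sRGB triple
#'
#' Scans all palettes in order and returns the entry minimizing
#' [color_distance()]; ties are broken by palette order then entry order
#' (strictly-better-wins scan).
#'
#' @param palettes Named list of palettes from [load_palettes()].
#' @param srgb Integer sRGB triple.
#' @param metric Distance metric passed to [color_distance()].
#' @return List with `palette` (name), `label`, `srgb` and `distance`.
#' @export
nearest_palette_color <- function(palettes, srgb,
                                  metric = c("euclidean", "redmean")) {
  metric <- match.arg(metric)
  if (!length(palettes)) {
    stop_charrec("no palettes loaded", class = "state")
  }
  check_srgb(srgb)
  best <- NULL
  for (p in palettes) {
    for (cc in p$colors) {
      d <- color_distance(srgb, cc$srgb, metric)
      if (is.null(best) || d < best$distance) {
        best <- list(palette = p$name, label = cc$label, srgb = cc$srgb,
                     distance = d)
      }
    }
  }
  best
}
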