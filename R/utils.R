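# Minimal deterministic SVG emission and TSV helpers shared by the
# heatmap and treemap renderers. Coordinates are fixed to 3 decimals so
# identical inputs give byte-identical files.

.fmt <- function(x) sprintf("%.3f", x)

.svgOpen <- function(width, height) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            .fmt(width), .fmt(height), .fmt(width), .fmt(height)))
}

.svgClose <- function() "</svg>"

.svgRect <- function(x, y, w, h, fill = "none", stroke = "none",
                     strokeWidth = 1, class = NULL) {
  sprintf(paste0("<rect%s x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
                 "fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>"),
          if (is.null(class)) "" else sprintf(" class=\"%s\"", class),
          .fmt(x), .fmt(y), .fmt(w), .fmt(h), fill, stroke, .fmt(strokeWidth))
}

.svgCircle <- function(cx, cy, r, fill, stroke = "none", class = NULL) {
  sprintf(paste0("<circle%s cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" ",
                 "stroke=\"%s\"/>"),
          if (is.null(class)) "" else sprintf(" class=\"%s\"", class),
          .fmt(cx), .fmt(cy), .fmt(r), fill, stroke)
}

.svgLine <- function(x1, y1, x2, y2, stroke, strokeWidth = 1, class = NULL) {
  sprintf(paste0("<line%s x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                 "stroke=\"%s\" stroke-width=\"%s\"/>"),
          if (is.null(class)) "" else sprintf(" class=\"%s\"", class),
          .fmt(x1), .fmt(y1), .fmt(x2), .fmt(y2), stroke, .fmt(strokeWidth))
}

.svgText <- function(x, y, text, anchor = "start", size = 10, rotate = 0) {
  transform <- if (rotate != 0)
    sprintf(" transform=\"rotate(%s %s %s)\"", .fmt(rotate), .fmt(x), .fmt(y))
  else ""
  sprintf(paste0("<text x=\"%s\" y=\"%s\" text-anchor=\"%s\" ",
                 "font-size=\"%s\" font-family=\"sans-serif\"%s>%s</text>"),
          .fmt(x), .fmt(y), anchor, .fmt(size), transform, text)
}

.rgbHex <- function(m) grDevices::rgb(m[, 1], m[, 2], m[, 3],
                                      maxColorValue = 255)

#' Write a data.frame as a tab-separated table
#'
#' @param df a data.frame.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeTsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tab-separated table with a header
#'
#' @param file input path.
#' @return data.frame.
#' @export
readTsv <- function(file) read.delim(file, stringsAsFactors = FALSE)
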