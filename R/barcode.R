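# Barcode: z-normalized 1D intensity trace with pixel scale and provenance

#' Construct a barcode
#'
#' A barcode is a z-normalized 1D fluorescence intensity profile along a DNA
#' molecule (experimental) or predicted from sequence (theoretical), with a
#' pixel scale (bp per pixel) and, when known, source genome coordinates
#' (0-based, half-open).
#'
#' @param values numeric intensities per pixel (length >= 2).
#' @param bp_per_pixel pixel scale in bp.
#' @param origin `"theory"` or `"experiment"`.
#' @param chrom,bp_start,bp_end optional source coordinates.
#' @param normalize z-normalize `values` (default TRUE).
#' @return object of class `cb_barcode` (numeric vector with attributes).
#' @export
barcode <- function(values, bp_per_pixel, origin = c("experiment", "theory"),
                    chrom = NA_character_, bp_start = NA_real_,
                    bp_end = NA_real_, normalize = TRUE) {
  origin <- match.arg(origin)
  stopifnot(is.numeric(values), length(values) >= 2, bp_per_pixel > 0)
  v <- if (normalize) z_normalize(values) else as.numeric(values)
  structure(v, class = "cb_barcode", bp_per_pixel = bp_per_pixel,
            origin = origin, chrom = chrom,
            bp_start = bp_start, bp_end = bp_end)
}

#' @export
print.cb_barcode <- function(x, ...) {
  cat(sprintf("<cb_barcode> %d px @ %.2f bp/px (%s)", length(x),
              attr(x, "bp_per_pixel"), attr(x, "origin")))
  if (!is.na(attr(x, "chrom"))) {
    cat(sprintf(" %s:%s-%s", attr(x, "chrom"),
                format(attr(x, "bp_start"), big.mark = ","),
                format(attr(x, "bp_end"), big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.cb_barcode <- function(x, ...) {
  tibble(pixel = seq_along(unclass(x)) - 1L, value = as.numeric(x),
         bp_start = (seq_along(unclass(x)) - 1) * attr(x, "bp_per_pixel") +
           (attr(x, "bp_start") %||% 0))
}

#' Reverse (flip) a barcode
#'
#' Flipping mirrors the molecule, e.g. to model the unknown orientation of a
#' molecule in the nanochannel. Source coordinates are retained.
#'
#' @param b a `cb_barcode`.
#' @return the flipped `cb_barcode`.
#' @export
flip_barcode <- function(b) {
  stopifnot(inherits(b, "cb_barcode"))
  out <- b
  out[] <- rev(as.numeric(b))
  out
}

#' Cut a pixel window out of a barcode
#'
#' Extracts pixels `[start_px, end_px)` (0-based, half-open), re-normalizes,
#' and tracks the bp coordinates of the cut.
#'
#' @param b a `cb_barcode`.
#' @param start_px,end_px 0-based half-open pixel interval.
#' @return a `cb_barcode` fragment.
#' @export
cut_barcode <- function(b, start_px, end_px) {
  stopifnot(inherits(b, "cb_barcode"), start_px >= 0, end_px <= length(b),
            end_px - start_px >= 2)
  bpp <- attr(b, "bp_per_pixel")
  b0 <- attr(b, "bp_start") %||% 0
  if (is.na(b0)) b0 <- 0
  barcode(as.numeric(b)[(start_px + 1):end_px], bp_per_pixel = bpp,
          origin = attr(b, "origin"), chrom = attr(b, "chrom"),
          bp_start = b0 + start_px * bpp, bp_end = b0 + end_px * bpp)
}

#' @export
autoplot.cb_barcode <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pixel", y = "z-normalized intensity",
                  title = sprintf("%s barcode, %.0f bp/px",
                                  attr(object, "origin"),
                                  attr(object, "bp_per_pixel"))) +
    ggplot2::theme_minimal()
}
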