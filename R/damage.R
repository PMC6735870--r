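# second-channel (damage label) processing: average, ROI trace, background
# correction, peak calling, projection onto genome coordinates

#' Average an image stack
#'
#' Per-pixel mean over the frames of a raw second-channel image stack.
#'
#' @param stack a 3D numeric array (rows x cols x frames) or a list of
#'   equally-shaped matrices.
#' @return a matrix (the time-averaged image).
#' @export
average_stack <- function(stack) {
  if (is.list(stack)) {
    dims <- unique(lapply(stack, dim))
    if (length(stack) == 0 || length(dims) != 1) {
      abort_cb("stack frames must be non-empty and equally shaped",
               class = "cbmapr_bad_input")
    }
    stack <- array(unlist(stack), dim = c(dims[[1]], length(stack)))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  apply(stack, c(1, 2), mean)
}

#' Extract the ROI intensity trace of a molecule
#'
#' Transverse mean over a band of `width` pixels centered on the molecule's
#' center line, per longitudinal position.
#'
#' @param image averaged image matrix (rows = transverse, cols =
#'   longitudinal).
#' @param center_row 1-based row index of the molecule center line.
#' @param width band width in pixels (odd; default 5).
#' @return numeric trace along the molecule.
#' @export
roi_trace <- function(image, center_row, width = 5) {
  stopifnot(is.matrix(image), width >= 1, width %% 2 == 1)
  h <- (width - 1) / 2
  if (center_row - h < 1 || center_row + h > nrow(image)) {
    abort_cb("ROI band falls outside the image", class = "cbmapr_bad_input")
  }
  colMeans(image[(center_row - h):(center_row + h), , drop = FALSE])
}

#' Background-correct and normalize a damage trace
#'
#' Smooths the ROI trace with a Gaussian filter (default sd 8 px), subtracts
#' the background trace extracted from a parallel band offset above the ROI,
#' and normalizes the corrected trace by its maximum. If the trace is
#' indistinguishable from its background the result is flagged
#' all-background instead of being normalized.
#'
#' @param trace ROI trace ([roi_trace()]).
#' @param background above-ROI background trace (same length).
#' @param sigma Gaussian filter standard deviation in pixels (default 8).
#' @param mode `"smooth_then_subtract"` (default): smooth the signal trace,
#'   subtract the raw background; `"subtract_smoothed_background"`: subtract
#'   a Gaussian-smoothed background from the raw trace.
#' @return object of class `cb_damage_trace`: numeric trace with max 1 when
#'   signal is present; `attr(, "all_background")` flags signal-free traces.
#' @export
background_correct <- function(trace, background, sigma = 8,
                               mode = c("smooth_then_subtract",
                                        "subtract_smoothed_background")) {
  mode <- match.arg(mode)
  if (length(trace) != length(background)) {
    abort_cb("trace and background must have the same length",
             class = "cbmapr_bad_input")
  }
  corrected <- if (mode == "smooth_then_subtract") {
    gaussian_smooth(trace, sigma) - background
  } else {
    trace - gaussian_smooth(background, sigma)
  }
  mx <- max(corrected)
  # no signal: the corrected maximum is indistinguishable from the residual
  # fluctuation level (robust MAD), as for a trace equal to its background
  scale_ref <- max(abs(trace), abs(background), 1e-300)
  all_bg <- mx <= max(4 * mad(corrected), 1e-12 * scale_ref)
  out <- if (all_bg) corrected else corrected / mx
  structure(out, class = "cb_damage_trace", all_background = all_bg,
            background = background, sigma = sigma)
}

#' Call peaks in a normalized damage trace
#'
#' Local maxima above `min_height` (fraction of the trace maximum), greedily
#' thinned so that retained peaks are at least `min_separation` pixels
#' apart (highest peaks kept first).
#'
#' @param trace a `cb_damage_trace` (or numeric trace).
#' @param min_height minimum peak height as a fraction of the trace maximum
#'   (default 0.3).
#' @param min_separation minimum distance between called peaks in pixels
#'   (default 4).
#' @return tibble with `peak_px` (0-based) and `height`; zero rows when no
#'   peaks (e.g. flagged all-background traces).
#' @export
call_peaks <- function(trace, min_height = 0.3, min_separation = 4) {
  v <- as.numeric(trace)
  empty <- tibble(peak_px = integer(), height = numeric())
  if (isTRUE(attr(trace, "all_background")) || length(v) < 3) return(empty)
  mx <- max(v)
  if (mx <= 0) return(empty)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE)
  cand <- which(is_max & v >= min_height * mx)
  if (length(cand) == 0) return(empty)
  cand <- cand[order(-v[cand], cand)]
  kept <- integer()
  for (p in cand) {
    if (all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  tibble(peak_px = kept - 1L, height = v[kept])
}

#' Project damage peaks onto genome coordinates
#'
#' Maps peak pixel positions along the molecule onto reference bp
#' coordinates through the molecule's match result: pixels are scaled by the
#' matched stretch factor, the pixel axis is reversed for flipped
#' placements, and reference pixels convert to bp via the reference pixel
#' scale. Peaks outside the matched interval are flagged, not dropped.
#'
#' @param peaks tibble from [call_peaks()] (column `peak_px`, 0-based in the
#'   molecule's own pixel frame).
#' @param match one-row match tibble from [best_match()].
#' @return tibble with `chrom`, `bp_start`, `bp_end` (one reference pixel
#'   wide, 0-based half-open), `strand`, `peak_px`, `out_of_bounds`.
#' @export
peaks_to_genome <- function(peaks, match) {
  stopifnot(nrow(match) == 1, !is.na(match$orientation))
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), bp_start = numeric(),
                  bp_end = numeric(), strand = character(),
                  peak_px = integer(), out_of_bounds = logical()))
  }
  bpp <- match$bp_per_pixel
  n_s <- match$query_stretched_px
  px_stretched <- peaks$peak_px * match$stretch
  ref_px <- if (match$orientation == "forward") {
    match$start_px + px_stretched
  } else {
    match$start_px + (n_s - 1) - px_stretched
  }
  oob <- peaks$peak_px < 0 | peaks$peak_px >= match$query_px
  bp <- ref_px * bpp
  tibble(chrom = match$chrom, bp_start = round(bp),
         bp_end = round(bp) + round(bpp),
         strand = if (match$orientation == "forward") "+" else "-",
         peak_px = peaks$peak_px, out_of_bounds = oob)
}
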