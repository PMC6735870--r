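# kymograph reduction: molecule segmentation, row alignment, time-averaging

#' Construct a kymograph
#'
#' A kymograph is a frames x pixels intensity matrix for one molecule; each
#' row is the intensity along the molecule in one time frame.
#'
#' @param mat numeric matrix (rows = time frames).
#' @return object of class `cb_kymograph`.
#' @export
kymograph <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), nrow(mat) >= 1, ncol(mat) >= 2)
  structure(mat, class = c("cb_kymograph", class(mat)),
            shifts = rep(0L, nrow(mat)), aligned = FALSE)
}

#' @export
print.cb_kymograph <- function(x, ...) {
  cat(sprintf("<cb_kymograph> %d frame(s) x %d px%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "aligned"))) " (aligned)" else ""))
  invisible(x)
}

#' @export
as_tibble.cb_kymograph <- function(x, ...) {
  m <- unclass(x)
  tibble(frame = rep(seq_len(nrow(m)), each = ncol(m)),
         pixel = rep(seq_len(ncol(m)) - 1L, nrow(m)),
         intensity = as.numeric(t(m)))
}

#' @export
autoplot.cb_kymograph <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$frame,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "pixel", y = "frame") +
    ggplot2::theme_minimal()
}

#' Locate the molecule in a single intensity row
#'
#' Finds the extent of a molecule as the interval where intensity exceeds the
#' half-maximum between the background level (median of the row flanks) and
#' the molecule plateau (median of the central region).
#'
#' @param row numeric intensity trace (length >= 8).
#' @param k detection threshold: the plateau must exceed background by
#'   `k` times the flank noise (MAD) to count as a molecule.
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels (default 2);
#'   bridges the dark AT-rich dips of a barcode so they are not mistaken
#'   for molecule ends. Set 0 for none.
#' @return integer `c(left, right)`, a 0-based half-open pixel interval, or
#'   `NULL` if no molecule is detected.
#' @details The interval runs from the first to the last half-max crossing
#'   of the smoothed trace: a barcode legitimately dips to background level
#'   inside AT-rich regions, so interior below-threshold stretches are part
#'   of the molecule, not gaps.
#' @export
segment_molecule <- function(row, k = 3, smooth_sigma = 2) {
  stopifnot(is.numeric(row), length(row) >= 8)
  n <- length(row)
  sm <- if (smooth_sigma > 0) gaussian_smooth(row, smooth_sigma) else row
  nf <- max(2L, floor(n / 16))
  flanks <- c(head(sm, nf), tail(sm, nf))
  bg <- median(flanks)
  noise <- mad(flanks)   # on the same (smoothed) scale as the plateau test
  mid <- sm[floor(n / 3):ceiling(2 * n / 3)]
  plateau <- median(mid)
  if (plateau <= bg + k * noise || plateau <= bg) return(NULL)
  half <- (bg + plateau) / 2
  above <- which(sm >= half)
  if (length(above) == 0) return(NULL)
  c(left = above[1] - 1L, right = above[length(above)])
}

# Pearson correlation of a candidate row placement against a reference trace
# over their overlapping, non-NA support; -Inf when overlap is too small or
# either side is constant
overlap_cor <- function(a, b, min_overlap = 8) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) return(-Inf)
  x <- a[ok]; y <- b[ok]
  if (sd(x) == 0 || sd(y) == 0) return(-Inf)
  cor(x, y)
}

# place a row into a width + 2*margin frame at integer shift s; no values
# are ever dropped, so alignment conserves row content exactly
place_row <- function(row, s, margin) {
  out <- rep(NA_real_, length(row) + 2 * margin)
  out[(margin + s + 1):(margin + s + length(row))] <- row
  out
}

#' Align kymograph rows
#'
#' Compensates small thermal fluctuations of the molecule inside the
#' nanochannel: each row is shifted by the integer pixel offset (bounded by
#' `max_shift`) that maximizes its Pearson correlation with the running
#' median of the rows already aligned. Rows are processed center-out, the
#' center row serving as the initial reference. Ties are broken toward the
#' smaller absolute offset, then toward the negative offset. Only positions
#' change; row values are conserved.
#'
#' @param kymo a [kymograph()] (>= 2 rows).
#' @param max_shift maximum absolute per-row shift in pixels (default 10).
#' @return an aligned `cb_kymograph` (vacated edge pixels are NA); per-row
#'   shifts are stored in `attr(, "shifts")`.
#' @export
align_kymograph <- function(kymo, max_shift = 10) {
  stopifnot(inherits(kymo, "cb_kymograph"))
  m <- unclass(kymo)
  n <- nrow(m)
  if (n < 2) return(kymo)
  if (ncol(m) < 2 * max_shift) {
    abort_cb("rows narrower than twice the maximum shift",
             class = "cbmapr_bad_input")
  }
  center <- ceiling(n / 2)
  order_rows <- order(abs(seq_len(n) - center), seq_len(n))
  aligned <- matrix(NA_real_, n, ncol(m) + 2 * max_shift)
  shifts <- integer(n)
  aligned[center, ] <- place_row(m[center, ], 0L, max_shift)
  cand <- order(abs(-max_shift:max_shift), -max_shift:max_shift)
  offs <- (-max_shift:max_shift)[cand]
  done <- center
  for (i in order_rows[-1]) {
    ref <- apply(aligned[done, , drop = FALSE], 2, median, na.rm = TRUE)
    ref[is.nan(ref)] <- NA_real_
    best <- -Inf; best_s <- 0L
    for (s in offs) {
      r <- overlap_cor(place_row(m[i, ], s, max_shift), ref)
      if (r > best) { best <- r; best_s <- s }
    }
    shifts[i] <- best_s
    aligned[i, ] <- place_row(m[i, ], best_s, max_shift)
    done <- c(done, i)
  }
  structure(aligned, class = class(kymo), shifts = shifts, aligned = TRUE)
}

#' Collapse an aligned kymograph into a time-averaged barcode
#'
#' Averages the first `n_frames` rows, cropped to the pixel span covered by
#' all used rows, and z-normalizes the result into an experimental barcode.
#' With `n_frames = 1` the first row is used directly and no alignment is
#' required.
#'
#' @param kymo a `cb_kymograph`; pass the output of [align_kymograph()] for
#'   multi-frame collapses.
#' @param n_frames number of leading frames to average (default 10,
#'   the standard setting).
#' @param bp_per_pixel pixel scale recorded on the barcode.
#' @param normalize z-normalize the averaged trace (default TRUE). Pass
#'   FALSE to keep raw intensities, e.g. to segment the molecule from its
#'   background first and normalize after cropping.
#' @return an experimental `cb_barcode`.
#' @export
collapse_kymograph <- function(kymo, n_frames = 10, bp_per_pixel = 800,
                               normalize = TRUE) {
  stopifnot(inherits(kymo, "cb_kymograph"))
  m <- unclass(kymo)
  if (n_frames < 1 || n_frames > nrow(m)) {
    abort_cb("n_frames must be between 1 and the number of rows",
             class = "cbmapr_bad_input")
  }
  used <- m[seq_len(n_frames), , drop = FALSE]
  keep <- colSums(is.na(used)) == 0
  if (sum(keep) < 2) {
    abort_cb("fewer than two pixels covered by all used frames",
             class = "cbmapr_bad_input")
  }
  avg <- colMeans(used[, keep, drop = FALSE])
  if (normalize && sd(avg) <= max(1e-12 * mean(abs(avg)), 1e-300)) {
    abort_cb("collapsed trace is (near) constant: degenerate barcode",
             class = "cbmapr_degenerate_barcode")
  }
  barcode(avg, bp_per_pixel = bp_per_pixel, origin = "experiment",
          normalize = normalize)
}
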