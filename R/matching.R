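# barcode-to-genome placement: sliding Pearson over position x flip x stretch

#' Calibrate the pixel scale with the lambda-DNA internal size reference
#'
#' Lambda phage DNA (48,502 bp) is co-loaded as an internal size reference;
#' its median extension in pixels fixes the bp-per-pixel conversion for the
#' experiment.
#'
#' @param lambda_pixels median extension of identified lambda molecules, in
#'   pixels.
#' @return bp per pixel (48502 / `lambda_pixels`).
#' @export
calibrate_bp_per_pixel <- function(lambda_pixels) {
  if (!is.numeric(lambda_pixels) || length(lambda_pixels) != 1 ||
      !is.finite(lambda_pixels) || lambda_pixels <= 0) {
    abort_cb("lambda extension must be a positive number of pixels",
             class = "cbmapr_bad_input")
  }
  48502 / lambda_pixels
}

#' Resample a barcode by a stretch factor
#'
#' Linear-interpolation resampling to `round(length * stretch)` pixels,
#' followed by re-z-normalization. Used to compensate variable DNA extension
#' between experiments.
#'
#' @param b a `cb_barcode`.
#' @param stretch stretch factor in `[0.5, 2]`.
#' @return the resampled `cb_barcode` (bp per pixel rescaled accordingly).
#' @export
resample_barcode <- function(b, stretch) {
  stopifnot(inherits(b, "cb_barcode"), stretch >= 0.5, stretch <= 2)
  n <- length(b)
  n2 <- round(n * stretch)
  if (n2 < 2) {
    abort_cb("resampled barcode would have fewer than 2 pixels",
             class = "cbmapr_bad_input")
  }
  if (n2 == n && stretch == 1) return(b)
  v <- approx(seq(0, 1, length.out = n), as.numeric(b),
              xout = seq(0, 1, length.out = n2))$y
  barcode(v, bp_per_pixel = attr(b, "bp_per_pixel") * n / n2,
          origin = attr(b, "origin"), chrom = attr(b, "chrom"),
          bp_start = attr(b, "bp_start"), bp_end = attr(b, "bp_end"))
}

# smallest FFT-friendly (2,3,5-smooth) length >= n
good_fft_length <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# precompute the reference-side quantities shared by every scan against r:
# zero-padded FFT (pad sized for queries up to n_max) and prefix sums
ref_scan_cache <- function(r, n_max) {
  m <- length(r)
  N <- good_fft_length(m + n_max)
  list(F = stats::fft(c(r, rep(0, N - m))), N = N, m = m,
       cs = c(0, cumsum(r)), cs2 = c(0, cumsum(r * r)))
}

# sliding-window Pearson correlation of q (and its reverse) against every
# start of the cached reference: cross terms via one FFT of the query,
# window means/variances via prefix sums. Windows with (numerically) zero
# variance get -Inf. NULL if the query does not fit.
scan_scores_cached <- function(rf, q) {
  n <- length(q); m <- rf$m
  if (n > m || n > rf$N - rf$m) return(NULL)
  sq <- sum(q); sq2 <- sum(q * q)
  vq <- sq2 - sq^2 / n
  idx <- seq_len(m - n + 1)
  sw <- rf$cs[idx + n] - rf$cs[idx]
  sw2 <- rf$cs2[idx + n] - rf$cs2[idx]
  vw <- sw2 - sw^2 / n
  Fq <- stats::fft(c(q, rep(0, rf$N - n)))
  # both cross-correlations (forward and reversed query) are real, so pack
  # them into the real/imaginary parts of a single inverse FFT
  y <- stats::fft(rf$F * (Conj(Fq) + 1i * Fq), inverse = TRUE) / rf$N
  cross_f <- Re(y)[idx]
  cross_r <- Im(y)[idx + n - 1]
  zv <- vw <= pmax(sw2, 1e-300) * 1e-12
  if (vq <= pmax(sq2, 1e-300) * 1e-12) zv <- rep(TRUE, length(vw))
  den <- sqrt(pmax(vq * vw, 1e-300))
  mk <- function(cross) {
    score <- (cross - sw * sq / n) / den
    score <- pmin(pmax(score, -1), 1)
    score[zv] <- -Inf
    score
  }
  list(forward = mk(cross_f), flipped = mk(cross_r))
}

scan_scores <- function(q, r) {
  sc <- scan_scores_cached(ref_scan_cache(r, length(q)), q)
  if (is.null(sc)) NULL else sc$forward
}

#' Sliding Pearson scan of a query barcode along a reference
#'
#' Computes the Pearson correlation coefficient between the query and every
#' same-length window of the reference, for both the original and the
#' flipped (reversed) query. Windows with zero intensity variance (e.g. long
#' runs of N in the reference) score `-Inf`.
#'
#' @param query,reference `cb_barcode`s (query no longer than reference).
#' @return tibble with `start` (0-based window start), `forward` and
#'   `flipped` correlation scores; zero rows if the query does not fit.
#' @export
pearson_scan <- function(query, reference) {
  q <- as.numeric(query); r <- as.numeric(reference)
  sc <- scan_scores_cached(ref_scan_cache(r, length(q)), q)
  if (is.null(sc)) {
    return(tibble(start = integer(), forward = numeric(), flipped = numeric()))
  }
  tibble(start = seq_along(sc$forward) - 1L, forward = sc$forward,
         flipped = sc$flipped)
}

# internal: scan a query over every reference at every grid stretch and both
# orientations; `mask_fn(chrom, n_starts, stretch)` may return 0-based starts
# to exclude. Returns the per-combination argmax candidates.
scan_candidates <- function(query, genome, grid, mask_fn = NULL) {
  stopifnot(inherits(query, "cb_barcode"))
  if (inherits(genome, "cb_barcode")) genome <- list(reference = genome)
  nq <- length(query)
  q0 <- as.numeric(query)
  n_max <- max(round(nq * max(grid)), nq) + 1L
  rows <- list()
  for (ci in seq_along(genome)) {
    ref <- genome[[ci]]
    rf <- ref_scan_cache(as.numeric(ref), n_max)
    for (s in grid) {
      n2 <- round(nq * s)
      if (n2 < 2 || n2 > rf$m) next
      qs <- if (n2 == nq) q0 else
        approx(seq(0, 1, length.out = nq), q0,
               xout = seq(0, 1, length.out = n2))$y
      sc2 <- scan_scores_cached(rf, qs)
      if (is.null(sc2)) next
      for (orient in c("forward", "flipped")) {
        sc <- sc2[[orient]]
        if (!is.null(mask_fn)) {
          drop <- mask_fn(names(genome)[ci], length(sc), s)
          drop <- drop[drop >= 0 & drop < length(sc)]
          if (length(drop)) sc[drop + 1] <- -Inf
        }
        best <- which.max(sc)
        if (!is.finite(sc[best])) next
        rows[[length(rows) + 1]] <- tibble(
          chrom = names(genome)[ci] %||% as.character(ci),
          chrom_index = ci, start_px = best - 1L,
          end_px = best - 1L + n2, orientation = orient,
          stretch = s, cmax = sc[best], query_px = nq,
          query_stretched_px = n2)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  bind_rows(rows)
}

#' Best genome placement of a barcode
#'
#' Global argmax of the Pearson match score over chromosome, start pixel,
#' orientation (forward/flipped) and stretch factor; the highest score
#' (C_max) is the best fit. Deterministic tie-break: lower chromosome index,
#' then lower start, then forward before flipped, then stretch nearer 1.
#'
#' @param query an experimental `cb_barcode`.
#' @param genome a `cb_genome` (named list of theory barcodes) or a single
#'   `cb_barcode`.
#' @param grid stretch factors, see [stretch_grid()].
#' @return one-row tibble (a match result): `chrom`, `start_px`, `end_px`
#'   (0-based half-open, reference pixels, leftmost-window convention for
#'   both orientations), `bp_start`, `bp_end`, `orientation`, `stretch`,
#'   `cmax`, `p_value` (NA until [add_p_values()]), `query_px`,
#'   `query_stretched_px`, `query_bp`, `bp_per_pixel`.
#' @export
best_match <- function(query, genome, grid = stretch_grid()) {
  cand <- scan_candidates(query, genome, grid)
  if (is.null(cand)) {
    abort_cb("no admissible placement for this query (unmappable query)",
             class = "cbmapr_unmappable")
  }
  if (inherits(genome, "cb_barcode")) genome <- list(reference = genome)
  best <- cand |>
    arrange(desc(.data$cmax), .data$chrom_index, .data$start_px,
            .data$orientation != "forward", abs(.data$stretch - 1)) |>
    head(1)
  bpp <- attr(genome[[best$chrom_index]], "bp_per_pixel")
  best |>
    mutate(bp_start = .data$start_px * bpp,
           bp_end = .data$end_px * bpp,
           bp_per_pixel = bpp,
           query_bp = .data$query_px * bpp,
           p_value = NA_real_) |>
    select("chrom", "start_px", "end_px", "bp_start", "bp_end",
           "orientation", "stretch", "cmax", "p_value", "query_px",
           "query_stretched_px", "query_bp", "bp_per_pixel")
}

#' Match a list of query barcodes against a genome
#'
#' Vectorized driver over [best_match()]; unmappable queries yield a row of
#' NAs so the output joins 1:1 with the input.
#'
#' @param queries list of `cb_barcode`s (optionally named).
#' @inheritParams best_match
#' @return tibble with one row per query (`query_id` column first).
#' @export
match_barcodes <- function(queries, genome, grid = stretch_grid()) {
  nm <- names(queries) %||% as.character(seq_along(queries))
  purrr::map2_dfr(queries, nm, function(q, id) {
    res <- tryCatch(best_match(q, genome, grid),
                    cbmapr_unmappable = function(e) {
                      tibble(chrom = NA_character_, start_px = NA_integer_,
                             end_px = NA_integer_, bp_start = NA_real_,
                             bp_end = NA_real_, orientation = NA_character_,
                             stretch = NA_real_, cmax = NA_real_,
                             p_value = NA_real_, query_px = length(q),
                             query_stretched_px = NA_integer_,
                             query_bp = NA_real_, bp_per_pixel = NA_real_)
                    })
    mutate(res, query_id = id, .before = 1)
  })
}

#' Classify placements as correct against known truth
#'
#' A placement is correct when it lands on the true chromosome within a
#' tolerance window of the true start (default 20 pixels). Both match and
#' truth use the leftmost-window (orientation-normalized) start convention,
#' so flipped placements at the mirrored coordinate compare correctly.
#'
#' @param matches match tibble ([best_match()] rows).
#' @param truth tibble with `chrom` and `start_px` (same coordinate system).
#' @param tol tolerance in pixels (default 20).
#' @return logical vector, one element per match row.
#' @export
is_correct_placement <- function(matches, truth, tol = 20) {
  stopifnot(nrow(matches) == nrow(truth))
  !is.na(matches$chrom) & matches$chrom == truth$chrom &
    abs(matches$start_px - truth$start_px) <= tol
}
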