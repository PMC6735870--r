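# in-silico mappability: fragment the genome, re-match with self-exclusion

#' Fragment a genome into fixed-length pieces
#'
#' Cuts each chromosome into consecutive fragments of `L_bp`. In `random`
#' mode the cut phase is drawn uniformly per chromosome (non-overlapping
#' fragments at a random offset, the in-silico analogue of randomly cutting
#' the genome); `tiled` mode starts at 0 for deterministic expectations.
#' Partial fragments at chromosome ends are discarded.
#'
#' @param genome a `cb_genome`.
#' @param L_bp fragment length in bp.
#' @param mode `"random"` or `"tiled"`.
#' @param seed RNG seed (required for `random` mode).
#' @return tibble with `fragment_id`, `chrom`, `bp_start`, `bp_end`,
#'   `start_px`, `end_px`.
#' @export
fragment_genome <- function(genome, L_bp, mode = c("random", "tiled"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "cb_genome"), L_bp > 0)
  bpp <- attr(genome, "bp_per_pixel")
  L_px <- round(L_bp / bpp)
  if (L_px < 2) abort_cb("fragment length below two pixels",
                         class = "cbmapr_bad_input")
  lens <- vapply(genome, length, 1L)
  if (all(lens < L_px)) {
    abort_cb("fragment length exceeds every chromosome",
             class = "cbmapr_bad_input")
  }
  offs <- if (mode == "random") {
    if (is.null(seed)) abort_cb("random mode requires a seed",
                                class = "cbmapr_bad_input")
    with_seed(seed, vapply(lens, function(l) sample.int(L_px, 1) - 1L, 1L))
  } else {
    rep(0L, length(lens))
  }
  out <- purrr::map_dfr(seq_along(genome), function(ci) {
    n_frag <- (lens[ci] - offs[ci]) %/% L_px
    if (n_frag < 1) return(NULL)
    s <- offs[ci] + (seq_len(n_frag) - 1L) * L_px
    tibble(chrom = names(genome)[ci], start_px = as.integer(s),
           end_px = as.integer(s + L_px))
  })
  out |>
    mutate(bp_start = .data$start_px * bpp, bp_end = .data$end_px * bpp,
           fragment_id = row_number(), .before = 1) |>
    select("fragment_id", "chrom", "bp_start", "bp_end", "start_px", "end_px")
}

#' Best off-origin match score of a fragment
#'
#' Runs the full position x flip x stretch search of a fragment barcode
#' against the genome, masking out every start within `exclusion` pixels of
#' the fragment's own origin (on its origin chromosome, both orientations in
#' leftmost-window coordinates), and returns the best remaining placement.
#'
#' @param frag_barcode the fragment's `cb_barcode`.
#' @param genome a `cb_genome`.
#' @param origin list or one-row tibble with `chrom` and `start_px`.
#' @param grid stretch factors.
#' @param exclusion half-width of the masked window around the origin
#'   (pixels, default 20).
#' @return one-row match tibble (as [best_match()]).
#' @export
self_excluded_cmax <- function(frag_barcode, genome, origin,
                               grid = stretch_grid(), exclusion = 20) {
  stopifnot(!is.null(origin$chrom), !is.null(origin$start_px))
  mask_fn <- function(chrom, n_starts, stretch) {
    if (!identical(chrom, origin$chrom)) return(integer())
    seq(origin$start_px - exclusion, origin$start_px + exclusion)
  }
  cand <- scan_candidates(frag_barcode, genome, grid, mask_fn = mask_fn)
  if (is.null(cand)) {
    abort_cb("no admissible off-origin placement", class = "cbmapr_unmappable")
  }
  best <- cand |>
    arrange(desc(.data$cmax), .data$chrom_index, .data$start_px,
            .data$orientation != "forward", abs(.data$stretch - 1)) |>
    head(1)
  bpp <- attr(genome, "bp_per_pixel")
  best |>
    mutate(bp_start = .data$start_px * bpp, bp_end = .data$end_px * bpp,
           bp_per_pixel = bpp) |>
    select("chrom", "start_px", "end_px", "bp_start", "bp_end",
           "orientation", "stretch", "cmax", "bp_per_pixel")
}

#' Genome mappability by fragmentation simulation
#'
#' Cuts the genome into `L_bp` fragments, computes each fragment's best
#' *off-origin* C_max, and classifies a fragment as non-mappable when that
#' score exceeds `threshold` (default 0.81, the empirical mean C_max of
#' mapped molecules): its barcode is then not unique genome-wide. Reports
#' the mappable genome fraction and the merged non-mappable intervals.
#'
#' @inheritParams fragment_genome
#' @param grid stretch factors used in re-matching.
#' @param threshold C_max uniqueness threshold (default 0.81).
#' @param exclusion self-exclusion window in pixels (default 20).
#' @return object of class `cb_mappability`: list with `fragments` (per
#'   fragment: origin, off-self C_max and location, mappable flag),
#'   `non_mappable` (merged half-open bp intervals), `fraction_mappable`,
#'   `L_bp`, `threshold`.
#' @export
classify_mappability <- function(genome, L_bp, mode = c("random", "tiled"),
                                 seed = NULL, grid = stretch_grid(),
                                 threshold = 0.81, exclusion = 20) {
  frags <- fragment_genome(genome, L_bp, mode = mode, seed = seed)
  res <- purrr::map_dfr(seq_len(nrow(frags)), function(i) {
    fr <- frags[i, ]
    fb <- cut_barcode(genome[[fr$chrom]], fr$start_px, fr$end_px)
    hit <- tryCatch(
      self_excluded_cmax(fb, genome, origin = fr, grid = grid,
                         exclusion = exclusion),
      cbmapr_unmappable = function(e) {
        tibble(chrom = NA_character_, start_px = NA_integer_, cmax = NA_real_)
      })
    tibble(off_self_cmax = hit$cmax, off_self_chrom = hit$chrom,
           off_self_start_px = hit$start_px)
  })
  frags <- dplyr::bind_cols(frags, res) |>
    mutate(mappable = is.na(.data$off_self_cmax) |
             .data$off_self_cmax <= threshold)
  fraction <- sum((frags$bp_end - frags$bp_start)[frags$mappable]) /
    sum(frags$bp_end - frags$bp_start)
  nm <- frags |> filter(!.data$mappable)
  intervals <- merge_intervals(nm$chrom, nm$bp_start, nm$bp_end)
  structure(list(fragments = frags, non_mappable = intervals,
                 fraction_mappable = fraction, L_bp = L_bp,
                 threshold = threshold),
            class = "cb_mappability")
}

# merge overlapping/adjacent half-open intervals per chromosome
merge_intervals <- function(chrom, start, end) {
  if (length(chrom) == 0) {
    return(tibble(chrom = character(), bp_start = numeric(),
                  bp_end = numeric()))
  }
  df <- tibble(chrom = chrom, bp_start = start, bp_end = end) |>
    arrange(.data$chrom, .data$bp_start)
  out <- list()
  cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    row <- df[i, ]
    if (row$chrom == cur$chrom && row$bp_start <= cur$bp_end) {
      cur$bp_end <- max(cur$bp_end, row$bp_end)
    } else {
      out[[length(out) + 1]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1]] <- cur
  bind_rows(out)
}

#' @export
print.cb_mappability <- function(x, ...) {
  cat(sprintf(
    "<cb_mappability> L = %s bp, C_max threshold %.2f: %.1f%% of fragmented bp mappable (%d/%d fragments)\n",
    format(x$L_bp, big.mark = ","), x$threshold, 100 * x$fraction_mappable,
    sum(x$fragments$mappable), nrow(x$fragments)))
  invisible(x)
}

#' @export
tidy.cb_mappability <- function(x, ...) x$fragments

#' @export
glance.cb_mappability <- function(x, ...) {
  tibble(L_bp = x$L_bp, threshold = x$threshold,
         n_fragments = nrow(x$fragments),
         n_non_mappable = sum(!x$fragments$mappable),
         fraction_mappable = x$fraction_mappable)
}

#' @export
autoplot.cb_mappability <- function(object, ...) {
  fr <- object$fragments
  ggplot2::ggplot(fr) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$bp_start / 1e6, xend = .data$bp_end / 1e6,
                   y = .data$chrom, yend = .data$chrom,
                   color = .data$mappable),
      linewidth = 4) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "grey60",
                                           `FALSE` = "red")) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = sprintf("mappable fraction %.1f%% at L = %s bp",
                                  100 * object$fraction_mappable,
                                  format(object$L_bp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' P-value versus fragment-length sweep
#'
#' For each fragment length in `L_grid_bp`, cuts noise-free fragments from
#' the genome, evaluates their C_max P-values against a per-length null
#' model, and reports the fraction passing the threshold. The smallest
#' length at which all sampled fragments pass estimates the minimum molecule
#' size for confident genome-wide placement.
#'
#' @param genome a `cb_genome`.
#' @param L_grid_bp fragment lengths to sweep (bp).
#' @param grid stretch factors.
#' @param null_R null draws per length.
#' @param seed RNG seed.
#' @param threshold P-value threshold (default 1e-6).
#' @param n_per_L fragments evaluated per length (subsampled tiling).
#' @param optics,ligand model parameters for the null draws.
#' @return tibble with `L_bp`, `n`, `fraction_passing`, `all_pass`;
#'   `attr(, "min_L_all_pass")` is the smallest all-passing length (NA if
#'   none).
#' @export
sweep_pvalue_length <- function(genome, L_grid_bp, grid = stretch_grid(),
                                null_R = 200, seed, threshold = 1e-6,
                                n_per_L = 20, optics = optics_params(),
                                ligand = ligand_params()) {
  out <- purrr::map_dfr(seq_along(L_grid_bp), function(k) {
    L <- L_grid_bp[k]
    frags <- fragment_genome(genome, L, mode = "tiled")
    idx <- with_seed(child_seed(seed, k), {
      sample(nrow(frags), min(n_per_L, nrow(frags)))
    })
    bars <- lapply(idx, function(i) {
      cut_barcode(genome[[frags$chrom[i]]], frags$start_px[i],
                  frags$end_px[i])
    })
    matches <- match_barcodes(bars, genome, grid)
    matches <- add_p_values(matches, genome, grid, R = null_R,
                            seed = child_seed(seed, 1000 + k),
                            optics = optics, ligand = ligand)
    pass <- !is.na(matches$p_value) & matches$p_value < threshold
    tibble(L_bp = L, n = length(pass), fraction_passing = mean(pass),
           all_pass = all(pass))
  })
  minL <- suppressWarnings(min(out$L_bp[out$all_pass]))
  attr(out, "min_L_all_pass") <- if (is.finite(minL)) minL else NA_real_
  out
}
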