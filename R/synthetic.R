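# synthetic ground-truth generators: genomes, planted fragments, kymographs

#' Pixel noise level that targets a mean C_max
#'
#' For a z-normalized signal with additive iid Gaussian pixel noise of sd
#' sigma, the expected correlation to the clean signal is
#' rho = 1 / sqrt(1 + sigma^2); inverting gives the noise sd that produces a
#' target mean C_max. The default experimental regime corresponds to
#' C_max ~ 0.81.
#'
#' @param target_cmax desired mean correlation in (0, 1).
#' @return noise standard deviation (in z-normalized intensity units).
#' @export
noise_sd_for_cmax <- function(target_cmax = 0.81) {
  stopifnot(target_cmax > 0, target_cmax < 1)
  sqrt(1 / target_cmax^2 - 1)
}

#' Generate a random genome
#'
#' iid bases at the given GC content (default 0.41, human-like), optionally
#' with a duplicated block (for mappability ground truth) and runs of N.
#' Deterministic per seed.
#'
#' @param length chromosome length(s) in bp (vector gives one record each).
#' @param gc GC content in `[0, 1]`.
#' @param seed RNG seed (mandatory).
#' @param names record names (default chr1, chr2, ...).
#' @param duplication optional `list(width=, src_start=, dest_start=)`:
#'   copies `width` bp starting at 0-based `src_start` of record 1 over the
#'   block at `dest_start` of record 1.
#' @param n_run optional `list(start=, width=)`: writes a run of N into
#'   record 1.
#' @return a `Biostrings::DNAStringSet`.
#' @export
random_genome <- function(length, gc = 0.41, seed, names = NULL,
                          duplication = NULL, n_run = NULL) {
  stopifnot(all(length >= 1), gc >= 0, gc <= 1)
  nm <- names %||% paste0("chr", seq_along(length))
  seqs <- with_seed(seed, {
    lapply(length, function(L) {
      sample(c("A", "C", "G", "T"), L, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    })
  })
  if (!is.null(duplication)) {
    d <- duplication
    src <- seqs[[1]][(d$src_start + 1):(d$src_start + d$width)]
    seqs[[1]][(d$dest_start + 1):(d$dest_start + d$width)] <- src
  }
  if (!is.null(n_run)) {
    seqs[[1]][(n_run$start + 1):(n_run$start + n_run$width)] <- "N"
  }
  out <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                         collapse = ""))
  names(out) <- nm
  out
}

#' Plant noisy fragments with known ground truth
#'
#' Cuts windows out of theory chromosome barcodes, perturbs each by a random
#' stretch, an optional flip, and additive iid pixel noise, and re-normalizes.
#' Truth records carry the origin, orientation and stretch of every
#' fragment, in the same leftmost-window pixel coordinates the matcher
#' reports, so recovery checks are a plain join.
#'
#' @param genome a `cb_genome` of theory barcodes.
#' @param n number of fragments.
#' @param length_px fragment length in pixels (before stretch perturbation).
#' @param noise_sd additive pixel noise sd (z-normalized units); see
#'   [noise_sd_for_cmax()].
#' @param stretch_range range of the uniform stretch perturbation (default
#'   +/-4%).
#' @param flip_prob probability a fragment is flipped (default 0.5).
#' @param seed RNG seed (mandatory).
#' @return list with `barcodes` (list of `cb_barcode`) and `truth` (tibble:
#'   `fragment_id`, `chrom`, `start_px`, `end_px`, `bp_start`, `bp_end`,
#'   `flipped`, `stretch`, `noise_sd`).
#' @export
plant_fragments <- function(genome, n, length_px, noise_sd = 0,
                            stretch_range = c(0.96, 1.04), flip_prob = 0.5,
                            seed) {
  stopifnot(inherits(genome, "cb_genome"), n >= 1, length_px >= 2)
  lens <- vapply(genome, length, 1L)
  ok <- which(lens >= length_px)
  if (length(ok) == 0) {
    abort_cb("no chromosome long enough for the fragment length",
             class = "cbmapr_bad_input")
  }
  bpp <- attr(genome, "bp_per_pixel")
  with_seed(seed, {
    bars <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = lens[ok] - length_px + 1)
      s0 <- sample.int(lens[ci] - length_px + 1, 1) - 1L
      frag <- cut_barcode(genome[[ci]], s0, s0 + length_px)
      stretch <- runif(1, stretch_range[1], stretch_range[2])
      b <- resample_barcode(frag, stretch)
      flipped <- runif(1) < flip_prob
      if (flipped) b <- flip_barcode(b)
      v <- as.numeric(b) + rnorm(length(b), 0, noise_sd)
      bars[[i]] <- barcode(v, bp_per_pixel = bpp / stretch,
                           origin = "experiment")
      truth[[i]] <- tibble(fragment_id = i, chrom = names(genome)[ci],
                           start_px = s0, end_px = s0 + length_px,
                           bp_start = s0 * bpp,
                           bp_end = (s0 + length_px) * bpp,
                           flipped = flipped, stretch = stretch,
                           noise_sd = noise_sd)
    }
    list(barcodes = bars, truth = bind_rows(truth))
  })
}

#' Simulate a kymograph (and optional damage channel) from a barcode
#'
#' Each frame is the barcode embedded in a background margin, shifted by a
#' cumulative integer random-walk drift (thermal fluctuation of the molecule
#' in the channel) plus additive iid Gaussian noise. The optional second
#' channel contains Gaussian spots at Poisson-placed damage sites, with
#' amplitude `snr` times the channel noise sd, sharing the same drift.
#'
#' @param b a `cb_barcode` (the molecule's true profile).
#' @param frames number of time frames.
#' @param drift_sd per-frame drift increment sd in pixels (default 1).
#' @param noise_sd additive pixel noise sd per frame.
#' @param seed RNG seed (mandatory).
#' @param margin background margin in pixels on each side (default: 15 or
#'   12% of the barcode length, whichever is larger, so downstream
#'   flank-based segmentation sees real background).
#' @param damage_rate expected damage sites per pixel (0 = no second
#'   channel).
#' @param snr damage spot amplitude over channel noise (default 10).
#' @param spot_sigma damage spot width in pixels (default 2).
#' @return list with `kymo` (a `cb_kymograph`), `damage` (matrix or NULL),
#'   `truth` (list: `drift` per frame, `damage_px` 0-based site positions
#'   within the barcode, `margin`).
#' @export
simulate_kymograph <- function(b, frames = 10, drift_sd = 1, noise_sd = 0,
                               seed, margin = NULL, damage_rate = 0,
                               snr = 10, spot_sigma = 2) {
  stopifnot(inherits(b, "cb_barcode"), frames >= 1)
  v <- as.numeric(b)
  n <- length(v)
  margin <- margin %||% max(15, ceiling(0.12 * n))
  w <- n + 2 * margin
  with_seed(seed, {
    drift <- if (frames == 1) 0L else
      cumsum(c(0L, as.integer(round(rnorm(frames - 1, 0, drift_sd)))))
    drift <- pmin(pmax(drift, -margin), margin)
    mk_frames <- function(profile, nsd) {
      m <- matrix(0, frames, w)
      for (f in seq_len(frames)) {
        row <- rep(0, w)
        row[(margin + drift[f] + 1):(margin + drift[f] + n)] <- profile
        m[f, ] <- row + rnorm(w, 0, nsd)
      }
      m
    }
    kymo <- kymograph(mk_frames(v - min(v), noise_sd))
    damage <- NULL
    damage_px <- integer()
    if (damage_rate > 0) {
      n_sites <- stats::rpois(1, damage_rate * n)
      damage_px <- sort(sample.int(n, min(n_sites, n)) - 1L)
      ch_noise <- if (noise_sd > 0) noise_sd else 0.02
      prof <- rep(0, n)
      for (p in damage_px) {
        x <- seq_len(n) - 1
        prof <- prof + snr * ch_noise * exp(-0.5 * ((x - p) / spot_sigma)^2)
      }
      damage <- mk_frames(prof, ch_noise)
    }
    list(kymo = kymo, damage = damage,
         truth = list(drift = drift, damage_px = damage_px, margin = margin))
  })
}
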