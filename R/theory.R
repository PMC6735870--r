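# theory barcodes: competitive-binding occupancy -> PSF-blurred pixel profile

# encode an A/C/G/T/N string as integers 0..3 (NA for N); rejects other
# characters; case-insensitive
encode_seq <- function(seq) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1)
  b <- utf8ToInt(seq)
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt(c("A"))] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt(c("C"))] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt(c("G"))] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt(c("T"))] <- 3L; lut[utf8ToInt("t")] <- 3L
  ok <- b <= 256
  code <- rep(NA_integer_, length(b))
  code[ok] <- lut[b[ok]]
  is_n <- b == utf8ToInt("N") | b == utf8ToInt("n")
  if (any(is.na(code) & !is_n)) {
    abort_cb("sequence contains characters outside {A,C,G,T,N}",
             class = "cbmapr_bad_sequence")
  }
  code
}

# per-start (linear) statistical weights for both ligand species.
# A window's weight is K * c; windows containing N (or off the end) get 0.
window_weights <- function(code, params) {
  L <- length(code)
  fn <- params$netropsin_footprint
  fy <- params$yoyo_footprint
  w_net <- numeric(L)
  w_yoyo <- numeric(L)

  if (L >= fn && params$netropsin_conc > 0) {
    ns <- L - fn + 1
    id <- rep(0, ns)
    for (j in seq_len(fn)) {
      id <- id + as.double(code[j:(ns + j - 1)]) * 4^(fn - j)
    }
    aff <- unname(params$affinity)
    w <- aff[id + 1] * params$netropsin_conc
    w[is.na(w)] <- 0                       # NA id: window contains N
    w_net[seq_len(ns)] <- w
  }
  if (L >= fy && params$yoyo_conc > 0 && params$yoyo_K > 0) {
    ns <- L - fy + 1
    nn <- cumsum(is.na(code))
    has_n <- (nn[seq_len(ns) + fy - 1] - c(0, nn)[seq_len(ns)]) > 0
    w <- rep(params$yoyo_K * params$yoyo_conc, ns)
    w[has_n] <- 0
    w_yoyo[seq_len(ns)] <- w
  }
  list(net = w_net, yoyo = w_yoyo)
}

#' Equilibrium YOYO-1 occupancy under netropsin competition
#'
#' Computes the per-basepair probability that a basepair is covered by a
#' bound YOYO-1 (or netropsin) molecule at binding equilibrium, from a
#' one-dimensional two-species hard-rod lattice model: a ligand occupies a
#' contiguous window of `footprint` basepairs, bound windows may not overlap,
#' and a window starting at position i carries statistical weight
#' K(i) * c (association constant times free-ligand concentration; netropsin's
#' K is sequence-dependent via the k-mer at the window start, YOYO-1's is
#' uniform). Marginal coverage is obtained exactly by a forward/backward
#' partition-function recursion in log space. Netropsin outcompetes YOYO-1 on
#' A/T tracts, which is why AT-rich regions are dark in the fluorescence
#' barcode.
#'
#' @param seq DNA sequence: a string over A/C/G/T/N (case-insensitive) or a
#'   Biostrings `DNAString`.
#' @param params a [ligand_params()] object.
#' @return object of class `cb_occupancy`: list with numeric vectors `yoyo`
#'   and `netropsin` (per-bp coverage probabilities), `log_Z`, and the
#'   parameters used.
#' @seealso [brute_force_occupancy()] for the exact enumeration oracle on
#'   short sequences; [render_theory_barcode()] to turn occupancy into a
#'   pixel barcode.
#' @export
yoyo_occupancy <- function(seq, params = ligand_params()) {
  stopifnot(inherits(params, "cb_ligand_params"))
  code <- encode_seq(seq)
  fmax <- max(params$netropsin_footprint, params$yoyo_footprint)
  if (length(code) < fmax) {
    abort_cb("sequence shorter than the largest ligand footprint",
             class = "cbmapr_bad_sequence")
  }
  w <- window_weights(code, params)
  res <- occupancy_core(w$net, w$yoyo,
                        params$netropsin_footprint, params$yoyo_footprint)
  structure(list(yoyo = res$yoyo, netropsin = res$netropsin,
                 log_Z = res$log_Z, length = length(code), params = params),
            class = "cb_occupancy")
}

#' @export
print.cb_occupancy <- function(x, ...) {
  cat(sprintf("<cb_occupancy> %d bp; mean YOYO coverage %.3f, mean netropsin coverage %.3f\n",
              x$length, mean(x$yoyo), mean(x$netropsin)))
  invisible(x)
}

#' @export
as_tibble.cb_occupancy <- function(x, ...) {
  tibble(position = seq_len(x$length) - 1L, yoyo = x$yoyo,
         netropsin = x$netropsin)
}

#' Exact occupancy by exhaustive enumeration (test oracle)
#'
#' Enumerates every legal non-overlapping placement configuration of both
#' ligand species on a short lattice and accumulates coverage weighted by the
#' product of window weights. Exponential in sequence length; intended as an
#' independent oracle for [yoyo_occupancy()] on sequences up to 20 bp.
#'
#' @inheritParams yoyo_occupancy
#' @return a `cb_occupancy` object.
#' @export
brute_force_occupancy <- function(seq, params = ligand_params()) {
  stopifnot(inherits(params, "cb_ligand_params"))
  code <- encode_seq(seq)
  L <- length(code)
  if (L > 20) {
    abort_cb("brute-force enumeration limited to sequences of <= 20 bp",
             class = "cbmapr_bad_sequence")
  }
  w <- window_weights(code, params)
  wn <- w$net
  wy <- w$yoyo
  fn <- params$netropsin_footprint
  fy <- params$yoyo_footprint

  Z <- 0
  cov_y <- numeric(L)
  cov_n <- numeric(L)
  rec <- function(i, w, ycov, ncov) {
    if (i > L) {
      Z <<- Z + w
      cov_y <<- cov_y + w * ycov
      cov_n <<- cov_n + w * ncov
      return(invisible())
    }
    rec(i + 1, w, ycov, ncov)                       # bp i left bare
    if (i + fn - 1 <= L && wn[i] > 0) {
      nc <- ncov; nc[i:(i + fn - 1)] <- 1
      rec(i + fn, w * wn[i], ycov, nc)
    }
    if (i + fy - 1 <= L && wy[i] > 0) {
      yc <- ycov; yc[i:(i + fy - 1)] <- 1
      rec(i + fy, w * wy[i], yc, ncov)
    }
  }
  rec(1, 1, numeric(L), numeric(L))
  structure(list(yoyo = cov_y / Z, netropsin = cov_n / Z, log_Z = log(Z),
                 length = L, params = params),
            class = "cb_occupancy")
}

#' Integrate an occupancy profile into camera pixels
#'
#' Blurs the per-bp YOYO-1 coverage with the Gaussian PSF (sigma expressed in
#' bp via the DNA extension) and integrates the blurred profile into pixels
#' of `bp_per_pixel`. Edge pixels use truncated-kernel renormalization so
#' molecule ends are not artificially dark.
#'
#' @param occ a `cb_occupancy` object (or bare numeric per-bp profile).
#' @param optics an [optics_params()] object.
#' @return tibble with `pixel` (0-based), `signal` (raw integrated kernel
#'   mass-weighted signal), `mass` (total kernel mass in the pixel) and
#'   `value` (= signal/mass, the renormalized pixel mean).
#' @export
pixelize_occupancy <- function(occ, optics = optics_params()) {
  stopifnot(inherits(optics, "cb_optics_params"))
  cov <- if (inherits(occ, "cb_occupancy")) occ$yoyo else as.numeric(occ)
  B <- optics$bp_per_pixel
  n_px <- floor(length(cov) / B)
  if (n_px < 2) {
    abort_cb("profile shorter than two pixels at this bp-per-pixel",
             class = "cbmapr_bad_params")
  }
  px <- pixelize_profile(cov, B, optics$psf_sigma_bp, as.integer(n_px))
  tibble(pixel = seq_len(n_px) - 1L, signal = px$signal, mass = px$mass,
         value = px$signal / px$mass)
}

#' Render a theoretical barcode from an occupancy profile
#'
#' @inheritParams pixelize_occupancy
#' @param chrom,bp_start source coordinates recorded on the barcode.
#' @return a z-normalized `cb_barcode` with `origin = "theory"`.
#' @export
render_theory_barcode <- function(occ, optics = optics_params(),
                                  chrom = NA_character_, bp_start = 0) {
  px <- pixelize_occupancy(occ, optics)
  B <- optics$bp_per_pixel
  barcode(px$value, bp_per_pixel = B, origin = "theory", chrom = chrom,
          bp_start = bp_start, bp_end = bp_start + nrow(px) * B)
}

#' Theoretical barcodes for every record of a genome
#'
#' Runs the competitive-binding model and PSF rendering over each record of a
#' FASTA file (or `DNAStringSet`), producing one theoretical chromosome
#' barcode per record. Runs of N get zero binding weight for both species and
#' appear dark.
#'
#' @param fasta path to a (optionally gzipped) FASTA file, or a
#'   `Biostrings::DNAStringSet`.
#' @param optics an [optics_params()] object.
#' @param ligand a [ligand_params()] object.
#' @return object of class `cb_genome`: named list of theory `cb_barcode`s,
#'   one per record.
#' @export
theory_genome <- function(fasta, optics = optics_params(),
                          ligand = ligand_params()) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else read_fasta(fasta)
  if (length(seqs) == 0) {
    abort_cb("FASTA contains no records", class = "cbmapr_bad_input")
  }
  min_bp <- 2 * optics$bp_per_pixel
  if (any(Biostrings::width(seqs) < min_bp)) {
    abort_cb("every record must span at least two pixels at this bp-per-pixel",
             class = "cbmapr_bad_input")
  }
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  bars <- lapply(seq_along(seqs), function(i) {
    occ <- yoyo_occupancy(as.character(seqs[[i]]), ligand)
    render_theory_barcode(occ, optics, chrom = nm[i], bp_start = 0)
  })
  structure(setNames(bars, nm), class = "cb_genome",
            bp_per_pixel = optics$bp_per_pixel)
}

#' @export
print.cb_genome <- function(x, ...) {
  cat(sprintf("<cb_genome> %d record(s), %d pixels total @ %.2f bp/px\n",
              length(x), sum(vapply(x, length, 1L)), attr(x, "bp_per_pixel")))
  invisible(x)
}
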