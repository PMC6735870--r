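# parameter constructors: ligand chemistry, optics, stretch search grid

#' Netropsin association-constant table
#'
#' Builds the per-k-mer association constant table used for the
#' sequence-dependent netropsin binding weight. Netropsin is a minor-groove
#' binder with strong preference for A/T tracts; the default table assigns a
#' high constant to k-mers consisting only of A/T and a low constant to all
#' others. Both values are configurable and the whole table can be replaced
#' by measured per-k-mer constants.
#'
#' @param footprint ligand footprint in bp (table covers all 4^footprint
#'   k-mers; default 4).
#' @param at_K association constant (1/M) for all-A/T k-mers.
#' @param other_K association constant (1/M) for every other k-mer.
#' @return named numeric vector of length `4^footprint` (names are k-mers in
#'   A/C/G/T order), values in 1/M.
#' @export
netropsin_affinity_table <- function(footprint = 4, at_K = 1e8, other_K = 1e5) {
  stopifnot(footprint >= 1, at_K >= 0, other_K >= 0)
  bases <- c("A", "C", "G", "T")
  # lexical order (last base varies fastest) so that positional encoding of a
  # k-mer as a base-4 integer indexes straight into this vector
  grid <- expand.grid(rep(list(bases), footprint), stringsAsFactors = FALSE)
  kmers <- apply(grid[, rev(seq_len(footprint)), drop = FALSE], 1, paste0, collapse = "")
  at <- !grepl("[CG]", kmers)
  setNames(ifelse(at, at_K, other_K), kmers)
}

#' Ligand binding parameters
#'
#' Parameters of the two-species competitive binding model: netropsin
#' (sequence-specific, non-fluorescent, blocks A/T tracts) and YOYO-1
#' (sequence-independent, fluorescent). Defaults follow the standard
#' labeling mix of 0.2 uM YOYO-1 and 60 uM netropsin, with free-ligand
#' concentrations approximated by totals (ligand excess at assay dilution).
#'
#' @param netropsin_conc netropsin concentration (M).
#' @param yoyo_conc YOYO-1 concentration (M).
#' @param netropsin_footprint,yoyo_footprint ligand footprints (bp).
#' @param affinity named numeric vector mapping k-mers (k =
#'   `netropsin_footprint`) to netropsin association constants (1/M); default
#'   [netropsin_affinity_table()].
#' @param yoyo_K sequence-independent YOYO-1 association constant (1/M).
#' @return object of class `cb_ligand_params`.
#' @export
ligand_params <- function(netropsin_conc = 60e-6, yoyo_conc = 0.2e-6,
                          netropsin_footprint = 4, yoyo_footprint = 4,
                          affinity = NULL, yoyo_K = 1e6) {
  stopifnot(netropsin_conc >= 0, yoyo_conc >= 0, yoyo_K >= 0,
            netropsin_footprint >= 1, yoyo_footprint >= 1)
  if (is.null(affinity)) affinity <- netropsin_affinity_table(netropsin_footprint)
  if (length(affinity) != 4^netropsin_footprint || any(affinity < 0)) {
    abort_cb("affinity table must give a non-negative constant for every k-mer of the netropsin footprint",
             class = "cbmapr_bad_params")
  }
  structure(list(netropsin_conc = netropsin_conc, yoyo_conc = yoyo_conc,
                 netropsin_footprint = as.integer(netropsin_footprint),
                 yoyo_footprint = as.integer(yoyo_footprint),
                 affinity = affinity, yoyo_K = yoyo_K),
            class = "cb_ligand_params")
}

#' Optics parameters
#'
#' Microscope point-spread function and sampling geometry connecting genome
#' coordinates (bp) to camera pixels. `bp_per_pixel = pixel_size / nm_per_bp`
#' unless overridden by a lambda-DNA calibration
#' ([calibrate_bp_per_pixel()]).
#'
#' @param psf_sigma Gaussian PSF standard deviation (nm).
#' @param nm_per_bp extension of channel-confined DNA (nm per bp).
#' @param pixel_size camera pixel size in the sample plane (nm).
#' @param bp_per_pixel optional override (bp per pixel), e.g. from the
#'   lambda-DNA internal size reference.
#' @return object of class `cb_optics_params`.
#' @export
optics_params <- function(psf_sigma = 110, nm_per_bp = 0.2, pixel_size = 160,
                          bp_per_pixel = NULL) {
  stopifnot(psf_sigma > 0, nm_per_bp > 0, pixel_size > 0)
  bpp <- bp_per_pixel %||% (pixel_size / nm_per_bp)
  stopifnot(bpp > 0)
  structure(list(psf_sigma = psf_sigma, nm_per_bp = nm_per_bp,
                 pixel_size = pixel_size, bp_per_pixel = bpp,
                 psf_sigma_bp = psf_sigma / nm_per_bp),
            class = "cb_optics_params")
}

#' Stretch search grid
#'
#' Symmetric grid of stretch factors applied to the experimental barcode
#' during matching, compensating variable DNA extension in nanochannels.
#' The default, up to 5% deviation in 1% steps, spans 0.95..1.05.
#'
#' @param max_deviation maximum fractional deviation from 1 (default 0.05).
#' @param step grid step as a fraction (default 0.01).
#' @return numeric vector of stretch factors, symmetric about and
#'   containing 1.
#' @export
stretch_grid <- function(max_deviation = 0.05, step = 0.01) {
  stopifnot(max_deviation >= 0, step > 0)
  k <- floor(max_deviation / step + 1e-9)
  1 + step * (-k:k)
}
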