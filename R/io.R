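# readers/writers: FASTA, BED6, barcode TSV, config

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` (gzip transparent,
#' case preserved; downstream encoding is case-insensitive).
#'
#' @param path path to a FASTA or FASTA.gz file.
#' @return a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_cb(paste0("no such file: ", path), class = "cbmapr_bad_input")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace token of each header, as mappers do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write match results as BED6(+1)
#'
#' Tab-separated BED, 0-based half-open; column 5 is C_max scaled to
#' `[0, 1000]`, the strand encodes orientation (+ forward, - flipped), and
#' the raw C_max is kept in column 7.
#'
#' @param matches match tibble (needs `chrom`, `bp_start`, `bp_end`,
#'   `orientation`, `cmax`; `query_id` is used as the name when present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(matches, path) {
  m <- matches[!is.na(matches$chrom), , drop = FALSE]
  if (nrow(m) > 0 && any(m$bp_start < 0 | m$bp_end < 0)) {
    abort_cb("negative coordinates in BED output", class = "cbmapr_bad_input")
  }
  name <- if ("query_id" %in% names(m)) as.character(m$query_id) else
    as.character(seq_len(nrow(m)))
  df <- data.frame(
    chrom = m$chrom, start = sprintf("%.0f", floor(m$bp_start)),
    end = sprintf("%.0f", ceiling(m$bp_end)), name = name,
    score = round(pmin(pmax(m$cmax, 0), 1) * 1000),
    strand = ifelse(m$orientation == "forward", "+", "-"),
    cmax = m$cmax)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6(+1) file written by [write_bed()]
#'
#' @param path path to the BED file.
#' @return tibble with `chrom`, `bp_start`, `bp_end`, `name`, `score`,
#'   `strand`, and `cmax` when present.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  nm <- c("chrom", "bp_start", "bp_end", "name", "score", "strand", "cmax")
  names(df) <- nm[seq_len(ncol(df))]
  as_tibble(df)
}

#' Write a barcode as annotated TSV
#'
#' Plain TSV (`pixel`, `value`) preceded by `#key=value` metadata lines
#' (pixel scale, origin, source coordinates) so any pipeline stage can be
#' run standalone on the file.
#'
#' @param b a `cb_barcode`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcode_tsv <- function(b, path) {
  stopifnot(inherits(b, "cb_barcode"))
  meta <- c(
    sprintf("#bp_per_pixel=%.10g", attr(b, "bp_per_pixel")),
    sprintf("#origin=%s", attr(b, "origin")),
    sprintf("#chrom=%s", attr(b, "chrom")),
    sprintf("#bp_start=%.10g", attr(b, "bp_start") %||% NA),
    sprintf("#bp_end=%.10g", attr(b, "bp_end") %||% NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("pixel\tvalue", con)
  writeLines(sprintf("%d\t%.12g", seq_along(b) - 1L, as.numeric(b)), con)
  invisible(path)
}

#' Read a barcode TSV written by [write_barcode_tsv()]
#'
#' @param path path to the TSV.
#' @return a `cb_barcode`.
#' @export
read_barcode_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  barcode(df$value, bp_per_pixel = as.numeric(meta[["bp_per_pixel"]]),
          origin = meta[["origin"]],
          chrom = if (meta[["chrom"]] %in% c("NA", "")) NA_character_ else
            meta[["chrom"]],
          bp_start = suppressWarnings(as.numeric(meta[["bp_start"]])),
          bp_end = suppressWarnings(as.numeric(meta[["bp_end"]])),
          normalize = FALSE)
}

#' Default pipeline configuration
#'
#' Full parameter tree of the pipeline with field-level defaults; see the
#' methods vignette for the rationale behind each value.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    ligand = list(netropsin_conc = 60e-6, yoyo_conc = 0.2e-6,
                  netropsin_footprint = 4, yoyo_footprint = 4,
                  at_K = 1e8, other_K = 1e5, yoyo_K = 1e6),
    optics = list(psf_sigma = 110, nm_per_bp = 0.2, pixel_size = 160,
                  bp_per_pixel = NULL),
    matching = list(max_deviation = 0.05, step = 0.01, tol_px = 20),
    significance = list(R = 200, bucket_px = 25, threshold = 1e-6),
    kymograph = list(frames = 10, max_shift = 10),
    damage = list(roi_width = 5, background_sigma = 8, min_height = 0.3,
                  min_separation = 4),
    simulate = list(genome_length = 4e6, gc = 0.41, n_molecules = 10,
                    fragment_px = 415, target_cmax = 0.81, frames = 10,
                    drift_sd = 1, damage_rate = 0, snr = 10)
  )
}

# recursively merge user config over defaults, rejecting unknown keys
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_cb(paste0("unknown config key(s): ",
                    paste0(path, unknown, collapse = ", ")),
             class = "cbmapr_bad_config")
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with any subset of the [default_config()] tree; unknown keys
#' are rejected, missing keys take defaults.
#'
#' @param path path to a YAML config file (NULL = all defaults).
#' @return resolved config list.
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_config(user, default_config())
}
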