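# umbrella pipeline: theory -> simulate/extract -> match -> p-value -> damage

config_objects <- function(config) {
  lig <- config$ligand
  list(
    ligand = ligand_params(
      netropsin_conc = lig$netropsin_conc, yoyo_conc = lig$yoyo_conc,
      netropsin_footprint = lig$netropsin_footprint,
      yoyo_footprint = lig$yoyo_footprint,
      affinity = netropsin_affinity_table(lig$netropsin_footprint,
                                          lig$at_K, lig$other_K),
      yoyo_K = lig$yoyo_K),
    optics = optics_params(
      psf_sigma = config$optics$psf_sigma,
      nm_per_bp = config$optics$nm_per_bp,
      pixel_size = config$optics$pixel_size,
      bp_per_pixel = config$optics$bp_per_pixel),
    grid = stretch_grid(config$matching$max_deviation, config$matching$step)
  )
}

#' Run the full mapping pipeline on synthetic or supplied inputs
#'
#' Executes the stages theory -> extract -> match -> p-value -> (damage) in
#' order. Without a FASTA a synthetic genome is generated from the
#' `simulate` config block; molecules are then simulated as kymographs from
#' planted genome fragments (frame noise set so the collapsed barcode hits
#' the configured target C_max), reduced to experimental barcodes, matched,
#' and filtered at the P-value threshold. Ground truth is joined back so
#' recovery can be read off directly. Deterministic given `config$seed`.
#'
#' @param config resolved config list ([default_config()]/[read_config()]).
#' @param fasta optional reference FASTA path or `DNAStringSet` (otherwise a
#'   random genome is simulated).
#' @param out_dir optional output directory: writes `matches.bed`,
#'   `matches.tsv`, `damage.bed` (when run) and `summary.json`.
#' @return list with `genome` (theory barcodes), `molecules` (per-molecule
#'   tibble: truth, match, P-value, correctness), `retained` (filtered
#'   matches), `damage` (projected peaks tibble or NULL), `counts`
#'   (per-stage tibble), `config`.
#' @export
run_pipeline <- function(config = default_config(), fasta = NULL,
                         out_dir = NULL) {
  obj <- config_objects(config)
  sim <- config$simulate
  seed <- config$seed

  seqs <- if (is.null(fasta)) {
    random_genome(sim$genome_length, gc = sim$gc,
                  seed = child_seed(seed, 1))
  } else if (inherits(fasta, "DNAStringSet")) fasta else read_fasta(fasta)

  genome <- theory_genome(seqs, obj$optics, obj$ligand)
  bpp <- attr(genome, "bp_per_pixel")

  # molecules: planted fragments rendered as kymographs, then re-extracted
  frames <- sim$frames
  frame_noise <- noise_sd_for_cmax(sim$target_cmax) * sqrt(frames)
  planted <- plant_fragments(genome, n = sim$n_molecules,
                             length_px = sim$fragment_px, noise_sd = 0,
                             stretch_range = c(1, 1), flip_prob = 0.5,
                             seed = child_seed(seed, 2))
  molecules <- vector("list", sim$n_molecules)
  damage_rows <- list()
  for (i in seq_len(sim$n_molecules)) {
    ksim <- simulate_kymograph(planted$barcodes[[i]], frames = frames,
                               drift_sd = sim$drift_sd,
                               noise_sd = frame_noise,
                               seed = child_seed(seed, 100 + i),
                               damage_rate = sim$damage_rate, snr = sim$snr)
    kal <- if (frames > 1) {
      align_kymograph(ksim$kymo, config$kymograph$max_shift)
    } else ksim$kymo
    bc_raw <- collapse_kymograph(kal, n_frames = frames, bp_per_pixel = bpp,
                                 normalize = FALSE)
    edges <- segment_molecule(as.numeric(bc_raw))
    bc <- if (!is.null(edges)) {
      cut_barcode(bc_raw, edges[["left"]], edges[["right"]])
    } else {
      barcode(as.numeric(bc_raw), bp_per_pixel = bpp, origin = "experiment")
    }
    molecules[[i]] <- bc
    if (!is.null(ksim$damage)) {
      damage_rows[[i]] <- list(sim = ksim, edges = edges)
    }
  }

  matches <- match_barcodes(molecules, genome, obj$grid)
  matches <- add_p_values(matches, genome, obj$grid,
                          R = config$significance$R,
                          seed = child_seed(seed, 3),
                          bucket_px = config$significance$bucket_px,
                          optics = obj$optics, ligand = obj$ligand)
  truth <- planted$truth
  matches$correct <- is_correct_placement(matches, truth,
                                          tol = config$matching$tol_px)
  molecules_tbl <- dplyr::bind_cols(
    truth |> dplyr::rename(true_chrom = "chrom", true_start_px = "start_px",
                           true_end_px = "end_px", true_flipped = "flipped",
                           true_bp_start = "bp_start", true_bp_end = "bp_end",
                           true_stretch = "stretch"),
    matches |> select(-"query_id")
  )
  retained <- filter_matches(matches, config$significance$threshold)

  damage_tbl <- NULL
  if (length(damage_rows) > 0) {
    damage_tbl <- purrr::map_dfr(seq_along(damage_rows), function(i) {
      dr <- damage_rows[[i]]
      if (is.null(dr) || is.na(matches$chrom[i])) return(NULL)
      dmg <- dr$sim$damage
      trace <- colMeans(dmg)
      margin <- dr$sim$truth$margin
      # crop the background margin so the trace is in molecule pixels
      n_mol <- ncol(dmg) - 2 * margin
      trace <- trace[(margin + 1):(margin + n_mol)]
      corr <- background_correct(trace, rep(0, length(trace)),
                                 sigma = config$damage$background_sigma)
      pk <- call_peaks(corr, config$damage$min_height,
                       config$damage$min_separation)
      if (nrow(pk) == 0) return(NULL)
      peaks_to_genome(pk, matches[i, ]) |>
        mutate(molecule = i, .before = 1)
    })
  } else if (sim$damage_rate > 0) {
    inform("damage stage skipped: no second channel present")
  }

  counts <- tibble(
    stage = c("molecules_in", "matched", "passing_threshold"),
    n = c(sim$n_molecules, sum(!is.na(matches$cmax)), nrow(retained)))

  out <- list(genome = genome, molecules = molecules_tbl,
              retained = retained, damage = damage_tbl, counts = counts,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(matches |> mutate(query_id = truth$fragment_id),
              file.path(out_dir, "matches.bed"))
    readr::write_tsv(molecules_tbl, file.path(out_dir, "matches.tsv"))
    if (!is.null(damage_tbl) && nrow(damage_tbl) > 0) {
      readr::write_tsv(damage_tbl, file.path(out_dir, "damage.tsv"))
    }
    jsonlite::write_json(
      list(seed = seed,
           n_molecules = sim$n_molecules,
           matched = sum(!is.na(matches$cmax)),
           passing_threshold = nrow(retained),
           retained_fraction = attr(retained, "retained_fraction"),
           correct_fraction = mean(matches$correct, na.rm = TRUE)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
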