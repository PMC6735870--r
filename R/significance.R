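# extreme-value significance of C_max against a randomized-sequence null

#' Sample the null distribution of C_max for a query length
#'
#' Draws `R` random DNA sequences of the bp length corresponding to
#' `query_px`, passes each through the full theory model (competitive
#' binding + PSF), and records the best match score (C_max) of the resulting
#' barcode against the genome under the same stretch/flip search. Running
#' the randomized barcodes through the theory model (rather than permuting
#' pixels) preserves the pixel autocorrelation imposed by the PSF.
#'
#' @param query_px query length in pixels.
#' @param genome a `cb_genome` of theory barcodes.
#' @param grid stretch factors used for matching.
#' @param R number of null draws (>= 100 for fitting).
#' @param seed RNG seed (mandatory; the sample is reproducible given seed).
#' @param optics,ligand model parameters; optics bp-per-pixel should match
#'   the genome's.
#' @param gc GC content of random sequences (0.5 = iid uniform bases).
#' @return tibble with `draw` and `cmax`.
#' @export
sample_null_cmax <- function(query_px, genome, grid = stretch_grid(), R = 100,
                             seed, optics = optics_params(),
                             ligand = ligand_params(), gc = 0.5) {
  stopifnot(inherits(genome, "cb_genome"), R >= 1, query_px >= 2)
  if (query_px > max(vapply(genome, length, 1L))) {
    abort_cb("every reference is shorter than the query",
             class = "cbmapr_bad_input")
  }
  bpp <- attr(genome, "bp_per_pixel")
  len_bp <- round((query_px + 1) * bpp)   # +1 px so flooring cannot undershoot
  cmax <- with_seed(seed, {
    vapply(seq_len(R), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), len_bp, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                 collapse = "")
      occ <- yoyo_occupancy(s, ligand)
      b <- render_theory_barcode(occ, optics)
      b <- cut_barcode(b, 0, query_px)
      res <- tryCatch(best_match(b, genome, grid),
                      cbmapr_unmappable = function(e) NULL)
      if (is.null(res)) -Inf else res$cmax
    }, numeric(1))
  })
  if (all(!is.finite(cmax))) {
    abort_cb("all null scans degenerate (zero-variance reference)",
             class = "cbmapr_degenerate_reference")
  }
  tibble(draw = seq_len(R), cmax = cmax)
}

#' Fit a Gumbel null model to a C_max sample
#'
#' C_max is the maximum of many correlated Pearson correlations, so its null
#' distribution is modeled with an extreme-value (Gumbel) law on the
#' Fisher-z transform of C_max, fitted by maximum likelihood. A
#' Kolmogorov-Smirnov distance against the fitted law is stored as a fit
#' diagnostic.
#'
#' @param sample output of [sample_null_cmax()] (or a numeric C_max vector).
#' @param query_px query length the sample was drawn at (recorded).
#' @param search_space optional descriptor (e.g. total reference pixels,
#'   orientations, stretch count), recorded for provenance.
#' @return object of class `cb_null_model` with fields `mu`, `beta`
#'   (location/scale on the Fisher-z scale), `R`, `ks`, `query_px`,
#'   `search_space`, and the transformed sample.
#' @export
fit_null <- function(sample, query_px = NA_integer_, search_space = NULL) {
  cmax <- if (is.data.frame(sample)) sample$cmax else as.numeric(sample)
  cmax <- cmax[is.finite(cmax)]
  if (length(cmax) < 100) {
    abort_cb("need at least 100 finite null draws to fit",
             class = "cbmapr_bad_input")
  }
  if (sd(cmax) <= 1e-12) {
    abort_cb("null sample has zero variance", class = "cbmapr_bad_input")
  }
  z <- atanh(pmin(pmax(cmax, -1 + 1e-12), 1 - 1e-12))
  # moment initialization, then Gumbel maximum likelihood on (mu, log beta)
  beta0 <- sd(z) * sqrt(6) / pi
  mu0 <- mean(z) - 0.5772156649 * beta0
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    u <- (z - mu) / beta
    length(z) * log(beta) + sum(u + exp(-u))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  mu <- fit$par[1]; beta <- exp(fit$par[2])
  ks <- suppressWarnings(
    ks.test(z, function(q) exp(-exp(-(q - mu) / beta)))$statistic
  )
  structure(list(mu = mu, beta = beta, R = length(cmax),
                 ks = unname(ks), query_px = query_px,
                 search_space = search_space, z = z, cmax = cmax,
                 convergence = fit$convergence),
            class = "cb_null_model")
}

#' @export
print.cb_null_model <- function(x, ...) {
  cat(sprintf(
    "<cb_null_model> Gumbel on Fisher-z(C_max): mu = %.4f, beta = %.4f (R = %d, KS = %.3f)\n",
    x$mu, x$beta, x$R, x$ks))
  invisible(x)
}

#' @export
tidy.cb_null_model <- function(x, ...) {
  tibble(term = c("mu", "beta"), estimate = c(x$mu, x$beta))
}

#' @export
glance.cb_null_model <- function(x, ...) {
  tibble(R = x$R, mu = x$mu, beta = x$beta, ks = x$ks,
         query_px = x$query_px, convergence = x$convergence)
}

#' @export
autoplot.cb_null_model <- function(object, ...) {
  df <- tibble(z = object$z)
  zz <- seq(min(df$z) - 3 * object$beta, max(df$z) + 3 * object$beta,
            length.out = 400)
  dens <- tibble(z = zz,
                 density = exp(-(zz - object$mu) / object$beta -
                                 exp(-(zz - object$mu) / object$beta)) /
                   object$beta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey70") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$z, y = .data$density),
                       color = "red") +
    ggplot2::labs(x = "Fisher-z(C_max)", y = "density",
                  title = "null C_max with fitted Gumbel") +
    ggplot2::theme_minimal()
}

#' Upper-tail P-value of an observed C_max
#'
#' `P(C >= cmax)` under the fitted Gumbel null on the Fisher-z scale;
#' strictly decreasing in `cmax`. Accurate deep into the tail (well below
#' 1e-6), where empirical quantiles cannot reach.
#'
#' @param cmax observed maximum correlation(s), in (-1, 1).
#' @param model a [fit_null()] model.
#' @return numeric vector of upper-tail probabilities.
#' @export
p_value <- function(cmax, model) {
  if (!inherits(model, "cb_null_model")) {
    abort_cb("model must be a fitted cb_null_model", class = "cbmapr_bad_input")
  }
  stopifnot(all(is.na(cmax) | (cmax >= -1 & cmax <= 1)))
  z <- atanh(pmin(pmax(cmax, -1 + 1e-12), 1 - 1e-12))
  t <- exp(-(z - model$mu) / model$beta)
  -expm1(-t)
}

#' Empirical-quantile P-value (fallback mode)
#'
#' Upper-tail probability estimated directly from the null sample, with the
#' usual (r+1)/(R+1) correction. Cannot resolve tails beyond ~1/R; use the
#' fitted [p_value()] for thresholds like 1e-6.
#'
#' @inheritParams p_value
#' @return numeric vector of empirical upper-tail probabilities.
#' @export
p_value_empirical <- function(cmax, model) {
  if (!inherits(model, "cb_null_model")) {
    abort_cb("model must be a fitted cb_null_model", class = "cbmapr_bad_input")
  }
  vapply(cmax, function(cm) {
    (sum(model$cmax >= cm) + 1) / (model$R + 1)
  }, numeric(1))
}

#' Attach P-values to match results
#'
#' Fits (and caches) one null model per query-length bucket (default 25 px)
#' and evaluates each match's C_max against the model for its bucket.
#'
#' @param matches match tibble (rows from [best_match()]/[match_barcodes()]).
#' @param genome,grid,optics,ligand as in [sample_null_cmax()].
#' @param R null draws per bucket.
#' @param seed RNG seed.
#' @param bucket_px bucket width in pixels for null-model caching.
#' @param cache optional environment reusing previously fitted models across
#'   calls (keyed by bucket and genome hash).
#' @return `matches` with the `p_value` column filled in.
#' @export
add_p_values <- function(matches, genome, grid = stretch_grid(), R = 200,
                         seed, bucket_px = 25, optics = optics_params(),
                         ligand = ligand_params(), cache = NULL) {
  if (nrow(matches) == 0) return(matches)
  cache <- cache %||% new.env(parent = emptyenv())
  ghash <- rlang::hash(lapply(genome, as.numeric))
  buckets <- as.integer(round(matches$query_px / bucket_px))
  p <- rep(NA_real_, nrow(matches))
  for (b in unique(buckets[!is.na(matches$cmax)])) {
    key <- paste(b, ghash, length(grid), R, sep = "|")
    if (!exists(key, envir = cache)) {
      len <- max(2L, as.integer(b * bucket_px))
      smp <- sample_null_cmax(len, genome, grid, R = R,
                              seed = child_seed(seed, b),
                              optics = optics, ligand = ligand)
      assign(key, fit_null(smp, query_px = len), envir = cache)
    }
    mdl <- get(key, envir = cache)
    sel <- which(buckets == b & !is.na(matches$cmax))
    p[sel] <- p_value(matches$cmax[sel], mdl)
  }
  matches$p_value <- p
  matches
}

#' Filter matches at a P-value threshold
#'
#' Retains matches with `p_value < threshold` (default 1e-6, the threshold
#' at which false positives vanish on validation data). The retained
#' fraction is attached as an attribute.
#'
#' @param matches match tibble with a filled `p_value` column.
#' @param threshold P-value threshold.
#' @return filtered tibble; `attr(, "retained_fraction")` gives the fraction
#'   of input rows retained.
#' @export
filter_matches <- function(matches, threshold = 1e-6) {
  if (nrow(matches) == 0) {
    out <- matches
    attr(out, "retained_fraction") <- NaN
    return(out)
  }
  if (any(is.na(matches$p_value) & !is.na(matches$cmax))) {
    abort_cb("matches must carry P-values; run add_p_values() first",
             class = "cbmapr_bad_input")
  }
  keep <- !is.na(matches$p_value) & matches$p_value < threshold
  out <- matches[keep, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}
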