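# molecule segmentation, row alignment, time-averaged collapse

test_that("segmentation finds top-hat edges exactly and rejects background", {
  row <- c(rep(0, 30), rep(1, 40), rep(0, 30))
  ed <- segment_molecule(row, smooth_sigma = 0)
  expect_equal(unname(ed), c(30L, 70L))

  withr::with_seed(21, {
    expect_null(segment_molecule(rnorm(100, 0, 0.1)))
  })

  # Gaussian-blurred top-hat: edges within 1 px of the closed-form half-max
  # crossings (erf profile crosses half-max at the original edges)
  x <- seq_len(100)
  blurred <- pnorm((x - 30.5) / 3) - pnorm((x - 70.5) / 3)
  ed2 <- segment_molecule(blurred, smooth_sigma = 0)
  expect_lte(abs(ed2[["left"]] - 30), 1)
  expect_lte(abs(ed2[["right"]] - 70), 1)
})

test_that("alignment recovers planted integer shifts exactly", {
  withr::with_seed(22, {
    base <- as.numeric(cut_barcode(th_small[[1]], 10, 110))
    shifts <- c(0L, 3L, -5L, 2L, -1L, 4L, -3L, 1L, 5L, -2L)
    rows <- t(vapply(shifts, function(s) {
      out <- rep(0, 130)
      out[(16 + s):(115 + s)] <- base - min(base)
      out
    }, numeric(130)))
    ka <- align_kymograph(kymograph(rows), max_shift = 6)
    rec <- attr(ka, "shifts")
    center <- ceiling(nrow(rows) / 2)
    expect_equal(rec, -(shifts - shifts[center]))
    # all aligned rows identical on the common support
    m <- unclass(ka)
    keep <- colSums(is.na(m)) == 0
    expect_true(all(apply(m[, keep], 2, function(col) diff(range(col)) == 0)))
  })
})

test_that("alignment conserves row content and handles edge cases", {
  withr::with_seed(23, {
    rows <- matrix(rnorm(5 * 80), 5, 80) + 5
    ka <- align_kymograph(kymograph(rows), max_shift = 8)
    m <- unclass(ka)
    for (i in 1:5) {
      expect_equal(sort(m[i, !is.na(m[i, ])]), sort(rows[i, ]))
    }
  })
  one <- kymograph(matrix(rnorm(50), 1))
  expect_identical(align_kymograph(one), one)
  expect_error(align_kymograph(kymograph(matrix(rnorm(30), 2, 15)),
                               max_shift = 10),
               class = "cbmapr_bad_input")
})

test_that("alignment improves row-to-row coherence under random-walk drift", {
  improved <- 0
  n_sim <- 20
  for (k in seq_len(n_sim)) {
    base <- cut_barcode(th_1mb[[1]], 200 + 10 * k, 350 + 10 * k)
    sim <- simulate_kymograph(base, frames = 10, drift_sd = 1,
                              noise_sd = 0.6, seed = 2000 + k)
    row_cor <- function(m) {
      cc <- vapply(2:nrow(m), function(i) {
        ok <- !is.na(m[i - 1, ]) & !is.na(m[i, ])
        cor(m[i - 1, ok], m[i, ok])
      }, numeric(1))
      mean(cc)
    }
    pre <- row_cor(unclass(sim$kymo))
    post <- row_cor(unclass(align_kymograph(sim$kymo)))
    improved <- improved + (post >= pre)
  }
  expect_gte(improved / n_sim, 0.95)
})

test_that("collapse averages, crops to common support, and z-normalizes", {
  base <- as.numeric(cut_barcode(th_small[[1]], 0, 60))
  rows <- matrix(rep(base, 4), 4, byrow = TRUE)
  bc <- collapse_kymograph(kymograph(rows), n_frames = 4)
  expect_equal(as.numeric(bc), (base - mean(base)) / sd(base),
               tolerance = 1e-12)
  expect_equal(mean(bc), 0, tolerance = 1e-9)
  expect_equal(sd(bc), 1, tolerance = 1e-9)

  # opposite zero-mean rows average to a constant: degenerate
  a <- rnorm(40)
  expect_error(collapse_kymograph(kymograph(rbind(a, -a)), n_frames = 2),
               class = "cbmapr_degenerate_barcode")
  expect_error(collapse_kymograph(kymograph(rows), n_frames = 0),
               class = "cbmapr_bad_input")
})

test_that("collapse noise scales as sigma over sqrt(n_frames)", {
  truth <- as.numeric(cut_barcode(th_1mb[[1]], 0, 1000))
  truth <- (truth - mean(truth)) / sd(truth)
  sigma <- 1
  res_sd <- vapply(c(1, 4, 16), function(nf) {
    withr::with_seed(24 + nf, {
      rows <- matrix(rep(truth, nf), nf, byrow = TRUE) +
        matrix(rnorm(nf * 1000, 0, sigma), nf)
      bc <- collapse_kymograph(kymograph(rows), n_frames = nf,
                               normalize = FALSE)
      sd(as.numeric(bc) - truth)
    })
  }, numeric(1))
  expect_equal(res_sd, sigma / sqrt(c(1, 4, 16)), tolerance = 0.2)
})

test_that("collapsed-barcode match quality is non-decreasing in frames", {
  n_mol <- 50
  cmax_by_frames <- matrix(NA_real_, n_mol, 3)
  for (i in seq_len(n_mol)) {
    start <- 100 + 20 * i
    frag <- cut_barcode(th_1mb[[1]], start, start + 120)
    sim <- simulate_kymograph(frag, frames = 16, drift_sd = 0,
                              noise_sd = 2.3, seed = 3000 + i, margin = 0)
    m <- unclass(sim$kymo)
    for (j in seq_along(c(1, 4, 16))) {
      nf <- c(1, 4, 16)[j]
      bc <- collapse_kymograph(kymograph(m), n_frames = nf)
      cmax_by_frames[i, j] <- cor(as.numeric(bc), as.numeric(frag))
    }
  }
  means <- colMeans(cmax_by_frames)
  expect_true(all(diff(means) > 0))
})
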