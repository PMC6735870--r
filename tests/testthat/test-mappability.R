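# genome fragmentation and mappability classification

test_that("tiled fragmentation gives exact counts; random mode is seeded", {
  g <- theory_genome(random_genome(10 * 80000, seed = 104))
  fr <- fragment_genome(g, 80000, mode = "tiled")
  expect_equal(nrow(fr), 10)
  expect_equal(fr$bp_start, seq(0, 9) * 80000)
  expect_true(all(fr$bp_end - fr$bp_start == 80000))

  r1 <- fragment_genome(g, 80000, mode = "random", seed = 7)
  r2 <- fragment_genome(g, 80000, mode = "random", seed = 7)
  expect_identical(r1, r2)
  expect_error(fragment_genome(g, 80000, mode = "random"),
               class = "cbmapr_bad_input")
  expect_error(fragment_genome(g, 1e9), class = "cbmapr_bad_input")
})

test_that("random fragmentation covers most of a long chromosome", {
  g <- theory_genome(random_genome(50 * 40000, seed = 105))
  cov <- vapply(1:20, function(s) {
    fr <- fragment_genome(g, 40000, mode = "random", seed = s)
    sum(fr$bp_end - fr$bp_start) / 2e6
  }, numeric(1))
  expect_gte(mean(cov), 0.9)
})

test_that("duplicated and unique genomes hit the 0 and 1 limits", {
  s <- random_genome(3e5, seed = 106)
  dup <- Biostrings::DNAStringSet(list(chr1 = s[[1]], chr2 = s[[1]]))
  g_dup <- theory_genome(dup)
  rep_dup <- classify_mappability(g_dup, 6e4, mode = "tiled")
  expect_equal(rep_dup$fraction_mappable, 0)

  g_uniq <- theory_genome(random_genome(3e5, seed = 107))
  rep_uniq <- classify_mappability(g_uniq, 6e4, mode = "tiled")
  expect_equal(rep_uniq$fraction_mappable, 1)
  expect_equal(nrow(rep_uniq$non_mappable), 0)
})

test_that("a duplicated block is flagged with the right granularity", {
  g <- theory_genome(random_genome(2e6, seed = 108,
                                   duplication = list(width = 4e5,
                                                      src_start = 2e5,
                                                      dest_start = 1.2e6)))
  rep <- classify_mappability(g, 1e5, mode = "tiled")
  # fragments fully inside either copy of the 400 kb block are non-mappable
  nm <- rep$non_mappable
  expect_true(nrow(nm) >= 1)
  in_block <- function(s, e) {
    (s >= 2e5 - 1e5 && e <= 6e5 + 1e5) ||
      (s >= 1.2e6 - 1e5 && e <= 1.6e6 + 1e5)
  }
  expect_true(all(mapply(in_block, nm$bp_start, nm$bp_end)))
  covered <- sum(pmin(nm$bp_end, 6e5) - pmax(nm$bp_start, 2e5) > 0) +
    sum(pmin(nm$bp_end, 1.6e6) - pmax(nm$bp_start, 1.2e6) > 0)
  expect_gte(covered, 2)      # both copies detected
  expect_equal(rep$fraction_mappable, (2e6 - 2 * 4e5) / 2e6,
               tolerance = 1e5 / 2e6 * 2)

  # threshold monotonicity on the same fragment scores
  frac_at <- function(th) {
    fr <- rep$fragments
    sum((fr$bp_end - fr$bp_start)[is.na(fr$off_self_cmax) |
                                    fr$off_self_cmax <= th]) /
      sum(fr$bp_end - fr$bp_start)
  }
  ths <- c(0.5, 0.7, 0.81, 0.95)
  expect_true(all(diff(vapply(ths, frac_at, numeric(1))) >= 0))
})

test_that("self-exclusion masks the origin and duplication restores C_max 1", {
  s <- random_genome(2.4e5, seed = 109)
  dup <- Biostrings::DNAStringSet(list(chr1 = s[[1]], chr2 = s[[1]]))
  g_dup <- theory_genome(dup)
  fb <- cut_barcode(g_dup$chr1, 50, 150)
  hit <- self_excluded_cmax(fb, g_dup, origin = list(chrom = "chr1",
                                                     start_px = 50))
  expect_equal(hit$cmax, 1, tolerance = 1e-9)   # exact copy on chr2
  expect_equal(hit$chrom, "chr2")

  g1 <- theory_genome(random_genome(2.4e5, seed = 110))
  fb1 <- cut_barcode(g1[[1]], 100, 220)
  hit1 <- self_excluded_cmax(fb1, g1, origin = list(chrom = "chr1",
                                                    start_px = 100))
  expect_lt(hit1$cmax, 0.6)

  # exclusion window covering the whole single reference: nothing admissible
  tiny <- theory_genome(random_genome(4e4, seed = 111))
  fb2 <- cut_barcode(tiny[[1]], 0, 30)
  expect_error(
    self_excluded_cmax(fb2, tiny, origin = list(chrom = "chr1",
                                                start_px = 0),
                       exclusion = 100),
    class = "cbmapr_unmappable")
})

test_that("mappable fraction is monotone in fragment length on unique genomes", {
  g <- theory_genome(random_genome(1.5e6, seed = 112))
  fracs <- vapply(c(1e5, 2e5, 3e5), function(L) {
    classify_mappability(g, L, mode = "tiled")$fraction_mappable
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # random and tiled modes agree on homogeneous genomes
  fr_r <- classify_mappability(g, 2e5, mode = "random", seed = 8)
  expect_lt(abs(fr_r$fraction_mappable - fracs[2]), 0.02)
})

test_that("p-value length sweep reports increasing pass fractions", {
  g <- theory_genome(random_genome(1.2e6, seed = 113))
  sw <- sweep_pvalue_length(g, c(6e4, 2.4e5), null_R = 120, seed = 9,
                            n_per_L = 4, threshold = 1e-4)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$fraction_passing >= 0 & sw$fraction_passing <= 1))
  expect_gte(sw$fraction_passing[2], sw$fraction_passing[1])
})
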