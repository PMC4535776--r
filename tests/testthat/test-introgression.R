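track_row <- function(pos, p, ind = "ind_01", hap = 1, chrom = "chr1") {
  data.frame(individual = ind, haplotype = hap, chrom = chrom, pos = pos,
             prob_sourceA = p, stringsAsFactors = FALSE)
}

test_that("SNP thresholding follows the certainty rule with unknowns", {
  tr <- track_row(c(100, 200, 300, 400), c(0.95, 0.5, 9, 0.91))
  calls <- call_introgressed_snps(tr, 0.9)
  expect_equal(calls$call, c(TRUE, FALSE, NA, TRUE))

  # threshold 1.0: only certain SNPs
  calls1 <- call_introgressed_snps(track_row(c(1, 2), c(1.0, 0.999)), 1.0)
  expect_equal(calls1$call, c(TRUE, FALSE))

  expect_error(call_introgressed_snps(track_row(1, 1.5)), "outside")
  expect_error(call_introgressed_snps(track_row(1, -0.1)), "outside")
  expect_error(call_introgressed_snps(track_row(1, 0.5), 0), "threshold")
})

test_that("block merging matches a brute-force interval scan", {
  # the worked case: T,T,F,T at 100..400
  tr <- track_row(c(100, 200, 300, 400), c(0.95, 0.92, 0.1, 0.99))
  b <- merge_blocks(call_introgressed_snps(tr))
  expect_equal(b$start, c(100, 400))
  expect_equal(b$end, c(201, 401))
  expect_equal(b$length, c(101, 1))

  # unknowns bridge: T, 9, T is one block over all three positions
  tr <- track_row(c(100, 200, 300), c(0.95, 9, 0.99))
  b <- merge_blocks(call_introgressed_snps(tr))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(100, 301))
  # but unknowns never start or end a block
  tr <- track_row(c(100, 200, 300), c(9, 0.95, 9))
  b <- merge_blocks(call_introgressed_snps(tr))
  expect_equal(c(b$start, b$end), c(200, 201))
  # and under the break policy they cut runs
  tr <- track_row(c(100, 200, 300), c(0.95, 9, 0.99))
  b <- merge_blocks(call_introgressed_snps(tr), gap_policy = "break")
  expect_equal(nrow(b), 2L)

  # all false -> empty
  b <- merge_blocks(call_introgressed_snps(track_row(1:3 * 100,
                                                     c(0, 0.2, 0.5))))
  expect_equal(nrow(b), 0L)

  # randomized agreement with the brute-force scan
  set.seed(77)
  for (rep in 1:25) {
    pos <- sort(sample(1:5000, 40))
    p <- sample(c(0, 0.5, 0.91, 0.97, 1, 9), 40, replace = TRUE)
    calls <- call_introgressed_snps(track_row(pos, p))
    got <- merge_blocks(calls)
    want <- brute_blocks(calls$pos, calls$call)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
    }
  }
})

test_that("block calling is idempotent under re-application", {
  set.seed(5150)
  pos <- seq(1000, 50000, by = 1000)
  p <- sample(c(0, 0.95, 9), length(pos), replace = TRUE)
  calls <- call_introgressed_snps(track_row(pos, p))
  b1 <- merge_blocks(calls)
  # re-derive a track from the blocks: SNPs inside blocks at prob 1
  inside <- vapply(pos, function(x)
    any(b1$start <= x & x < b1$end), logical(1))
  calls2 <- call_introgressed_snps(track_row(pos, as.numeric(inside)))
  b2 <- merge_blocks(calls2)
  expect_equal(b1[c("start", "end")], b2[c("start", "end")])
})

test_that("sweep-line copy counts equal per-bp brute force", {
  # two half-overlapping blocks -> segments with counts 1, 2, 1
  blocks <- rbind(
    track_blocks <- data.frame(chrom = "chr1", start = 100, end = 300,
                               individual = "a", haplotype = 1),
    data.frame(chrom = "chr1", start = 200, end = 400, individual = "b",
               haplotype = 1))
  class(blocks) <- c("introgression_blocks", "data.frame")
  prof <- copy_count_profile(blocks)
  nz <- prof[prof$n_copies > 0, ]
  expect_equal(nz$n_copies, c(1L, 2L, 1L))
  expect_equal(nz$start, c(100, 200, 300))
  expect_equal(nz$end, c(200, 300, 400))

  # randomized instances against brute-force per-bp counting
  set.seed(88)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    start <- sample(1:900, n)
    blocks <- data.frame(chrom = "chr1", start = start,
                         end = start + sample(10:100, n, replace = TRUE),
                         individual = paste0("i", seq_len(n)),
                         haplotype = 1)
    prof <- copy_count_profile(blocks, c(chr1 = 1000))
    bp <- brute_copy_counts(blocks, "chr1", 1000)
    expanded <- integer(1000)
    for (s in seq_len(nrow(prof)))
      expanded[seq(prof$start[s], prof$end[s] - 1)] <- prof$n_copies[s]
    expect_equal(expanded, bp)
    # breakpoints exactly at block boundaries
    expect_true(all(prof$start[-1] %in% c(blocks$start, blocks$end)))
  }

  # six identical blocks from six haplotypes -> one segment at 6 copies
  six <- data.frame(chrom = "chr1", start = 50, end = 150,
                    individual = rep(paste0("i", 1:3), each = 2),
                    haplotype = rep(1:2, 3))
  prof <- copy_count_profile(six)
  expect_equal(prof$n_copies[prof$start == 50], 6L)

  # overlapping blocks on one haplotype violate the invariant
  bad <- data.frame(chrom = "chr1", start = c(10, 50), end = c(100, 80),
                    individual = "a", haplotype = 1)
  expect_error(copy_count_profile(bad), "overlapping")

  # empty input with known chromosome: zero everywhere
  prof0 <- copy_count_profile(six[0, ], c(chr1 = 500))
  expect_equal(prof0$n_copies, 0L)
  expect_equal(prof0$end - prof0$start, 500)
})

test_that("genome fractions are correct and monotone in the copy threshold", {
  blocks <- data.frame(chrom = "chr1", start = 1, end = 1e7 + 1,
                       individual = "a", haplotype = 1)
  prof <- copy_count_profile(blocks, c(chr1 = 1e8))
  gs <- genome_fraction(prof, c(chr1 = 1e8), 1)
  expect_equal(gs$fraction, 0.10)

  # impossible copy count -> 0
  expect_equal(genome_fraction(prof, c(chr1 = 1e8), 7)$fraction, 0)

  # monotone non-increasing per-k table
  set.seed(99)
  n <- 20
  start <- sample(1:5e5, n)
  blocks <- data.frame(chrom = "chr1", start = start,
                       end = start + sample(1e3:1e5, n, replace = TRUE),
                       individual = rep(paste0("i", 1:5), 4),
                       haplotype = rep(rep(1:2, each = 5), 2))
  blocks <- blocks[!duplicated(blocks[c("individual", "haplotype")]) |
                     TRUE, ]
  prof <- copy_count_profile(merge_blocks(call_introgressed_snps(
    simulate_ancestry_tracks(blocks[1:8, ], c(chr1 = 1e6), 5, 500,
                             noise_sd = 0, seed = 3))), c(chr1 = 1e6))
  gs <- genome_fraction(prof, c(chr1 = 1e6), 1)
  expect_true(all(diff(gs$per_k$fraction) <= 1e-12))

  expect_error(genome_fraction(prof, c(chr2 = 1e6), 1), "absent")
})

test_that("fixed regions are maximal full-copy-number intervals", {
  # three individuals; one region covered by all six haplotypes
  hap_grid <- expand.grid(individual = paste0("i", 1:3), haplotype = 1:2,
                          stringsAsFactors = FALSE)
  blocks <- data.frame(chrom = "chr1", start = 1000, end = 5000,
                       hap_grid)
  # one haplotype also has a private extension
  blocks <- rbind(blocks, data.frame(chrom = "chr1", start = 5000,
                                     end = 6000, individual = "i1",
                                     haplotype = 1))
  prof <- copy_count_profile(blocks, c(chr1 = 10000))
  fr <- fixed_regions(prof, 6)
  expect_equal(nrow(fr), 1L)
  expect_equal(c(fr$start, fr$end), c(1000, 5000))

  # any haplotype missing -> not fixed
  fr5 <- fixed_regions(copy_count_profile(blocks[-1, ], c(chr1 = 10000)), 6)
  expect_equal(nrow(fr5), 0L)
})

test_that("noise-free synthetic tracks are recovered exactly; noisy ones to lattice resolution", {
  chrom_lengths <- c(chr1 = 2e5, chr2 = 1e5)
  spacing <- 1000
  truth <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 120000, 30000), end = c(50000, 160000, 80000),
    individual = c("ind_01", "ind_02", "ind_01"), haplotype = c(1, 2, 2))
  tr <- simulate_ancestry_tracks(truth, chrom_lengths, 2, spacing,
                                 noise_sd = 0, seed = 42)
  got <- merge_blocks(call_introgressed_snps(tr, 0.9))
  expect_equal(nrow(got), 3L)
  for (r in seq_len(nrow(truth))) {
    snapped <- snap_block_to_lattice(truth$start[r], truth$end[r], spacing,
                                     chrom_lengths[[truth$chrom[r]]])
    hit <- got[got$chrom == truth$chrom[r] &
                 got$individual == truth$individual[r] &
                 got$haplotype == truth$haplotype[r], ]
    expect_equal(c(hit$start, hit$end), snapped)
  }

  # modest noise: boundary recovery within one SNP spacing of the truth
  tr <- simulate_ancestry_tracks(truth, chrom_lengths, 2, spacing,
                                 noise_sd = 0.05, seed = 43)
  got <- merge_blocks(call_introgressed_snps(tr, 0.9))
  for (r in seq_len(nrow(truth))) {
    hit <- got[got$chrom == truth$chrom[r] &
                 got$individual == truth$individual[r] &
                 got$haplotype == truth$haplotype[r], ]
    expect_gt(nrow(hit), 0)
    expect_lt(abs(min(hit$start) - truth$start[r]), 2 * spacing)
    expect_lt(abs(max(hit$end) - truth$end[r]), 2 * spacing)
  }
})
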