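# Preprocessing: border exclusion, tiling, labeling, splits, subsampling.

make_flat_genome <- function(len, chroms = "c1") {
  seqs <- vapply(chroms, function(ch) random_dna(len, seed = utf8ToInt(ch)[2]),
                 character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
}

test_that("border exclusion removes a centered zone at each NMI border", {
  g <- make_flat_genome(3000)
  reg <- build_analysis_region(g, regions("c1", 1000, 2000), border_bp = 500)
  # zones [750,1250) and [1750,2250) are excised
  expect_equal(reg, regions(rep("c1", 3), c(0, 1250, 2250), c(750, 1750, 3000)))
})

test_that("border exclusion clips at chromosome bounds", {
  g <- make_flat_genome(3000)
  reg <- build_analysis_region(g, regions("c1", 0, 600), border_bp = 500)
  # left zone clipped to [0,250); right zone [350,850)
  expect_equal(reg, regions(c("c1", "c1"), c(250, 850), c(350, 3000)))
})

test_that("short NMIs lose their whole interior to overlapping zones", {
  g <- make_flat_genome(3000)
  nmi <- regions("c1", 1000, 1400) # length 400 < border_bp
  reg <- build_analysis_region(g, nmi, border_bp = 500)
  # union of [750,1250) and [1150,1650) removes [750,1650)
  expect_equal(reg, regions(c("c1", "c1"), c(0, 1650), c(750, 3000)))
  expect_equal(region_overlap_length(nmi, reg), 0)
})

test_that("NMIs on unknown chromosomes are rejected", {
  g <- make_flat_genome(3000)
  expect_error(build_analysis_region(g, regions("cX", 0, 100)), "absent")
})

test_that("tiling drops trailing fragments and N-rich windows", {
  g <- make_flat_genome(1600)
  w <- tile_windows(regions("c1", 0, 1600), g, width = 750)
  expect_equal(w$start, c(0, 750))
  expect_equal(w$end, c(750, 1500))
  expect_equal(nchar(w$seq), c(750, 750))

  expect_equal(nrow(tile_windows(regions("c1", 0, 749), g, width = 750)), 0)

  # a window with 100/750 N bases (13.3% > 10%) is discarded
  s <- random_dna(1500, seed = 3)
  substr(s, 100, 199) <- strrep("N", 100)
  gn <- Biostrings::DNAStringSet(c(c1 = s))
  w <- tile_windows(regions("c1", 0, 1500), gn, width = 750)
  expect_equal(w$start, 750)
})

test_that("window count equals sum of floor(len/width) minus N-filtered", {
  g <- make_flat_genome(10000)
  reg <- regions(rep("c1", 3), c(0, 2000, 5100), c(1600, 4999, 9000))
  w <- tile_windows(reg, g, width = 750, max_n_frac = 1)
  expect_equal(nrow(w), sum((c(1600, 2999, 3900) %/% 750)))
})

test_that("labels follow the >= 50% coverage rule with equality positive", {
  g <- make_flat_genome(1500)
  w <- tile_windows(regions("c1", 0, 750), g, width = 750)
  expect_equal(label_windows(w, regions("c1", 375, 800))$label, 1L)
  expect_equal(label_windows(w, regions("c1", 376, 800))$label, -1L)
  expect_equal(label_windows(w, regions("c1", 1000, 1200))$label, -1L)
})

test_that("labels are invariant under a joint constant coordinate shift", {
  win <- regions(rep("c1", 4), c(0, 750, 1500, 2250), c(750, 1500, 2250, 3000))
  nmi <- regions(c("c1", "c1"), c(100, 1700), c(900, 2600))
  shift <- 13570
  l1 <- label_windows(win, nmi)$label
  win2 <- regions(win$chrom, win$start + shift, win$end + shift)
  nmi2 <- regions(nmi$chrom, nmi$start + shift, nmi$end + shift)
  expect_equal(label_windows(win2, nmi2)$label, l1)
})

test_that("chromosome splits accumulate to the target fraction", {
  g <- make_flat_genome(1, chroms = paste0("c", 1:6))
  # weigh chromosomes by an explicit region set
  reg <- regions(paste0("c", 1:6), rep(0, 6), c(600, 300, 300, 200, 400, 200))
  sp <- split_chromosomes(g, reg, test_frac = 0.5, seed = 5)
  expect_setequal(c(sp$test_chroms, sp$train_chroms), paste0("c", 1:6))
  test_len <- sum(reg$end[reg$chrom %in% sp$test_chroms])
  expect_gte(test_len, 0.5 * sum(reg$end))
  expect_gt(length(sp$train_chroms), 0)
  expect_identical(sp, split_chromosomes(g, reg, 0.5, seed = 5))
})

test_that("degenerate chromosome splits error", {
  g1 <- make_flat_genome(1000, "c1")
  expect_error(split_chromosomes(g1, regions("c1", 0, 1000)), "single-chromosome")
  g2 <- make_flat_genome(1000, c("c1", "c2"))
  reg <- regions(c("c1", "c2"), c(0, 0), c(1000, 1000))
  expect_error(split_chromosomes(g2, reg, test_frac = 1.0), "no training")
})

test_that("tuning/training partition is disjoint, exhaustive, seeded", {
  w <- data.frame(chrom = "c1", start = seq(0, 99) * 10,
                  end = seq(0, 99) * 10 + 10, seq = "A",
                  stringsAsFactors = FALSE)
  tt <- split_tuning_training(w, frac = 0.5, seed = 2)
  expect_equal(nrow(tt$tuning), 50)
  expect_equal(nrow(tt$training), 50)
  expect_equal(sort(c(tt$tuning$start, tt$training$start)), w$start)
  expect_identical(tt, split_tuning_training(w, frac = 0.5, seed = 2))
  tt3 <- split_tuning_training(w[1:10, ], frac = 0.3, seed = 2)
  expect_equal(nrow(tt3$tuning), 3)
  expect_equal(nrow(tt3$training), 7)
})

test_that("balanced subsampling hits exact counts and falls back on few positives", {
  w <- data.frame(label = c(rep(1L, 40), rep(-1L, 500)), seq = "A")
  out <- subsample_balanced(w, total = 120, ratio = 5, seed = 1)
  expect_equal(sum(out$label == 1), 20)
  expect_equal(sum(out$label == -1), 100)
  expect_identical(out, subsample_balanced(w, total = 120, ratio = 5, seed = 1))

  # ratio-preserving fallback when positives are scarce
  w2 <- data.frame(label = c(rep(1L, 10), rep(-1L, 500)), seq = "A")
  expect_warning(out2 <- subsample_balanced(w2, total = 120, ratio = 5, seed = 1),
                 "positive")
  expect_equal(sum(out2$label == 1), 10)
  expect_equal(sum(out2$label == -1), 50)

  w3 <- data.frame(label = rep(-1L, 50), seq = "A")
  expect_error(subsample_balanced(w3, total = 12, ratio = 5), "no positive")
  expect_error(subsample_balanced(w, total = 100, ratio = 5))
})

test_that("no emitted window overlaps a border zone or masked-out base", {
  for (seed in c(31, 32)) {
    g <- small_synth("warm", 101)
    mask <- regions(names(g$genome), rep(0, 6),
                    Biostrings::width(g$genome) - 1357) # clip chromosome tails
    reg <- build_analysis_region(g$genome, g$nmis, mask = mask)
    w <- tile_windows(reg, g$genome)
    zones <- subtract_regions(complement_regions(reg, g$genome),
                              complement_regions(mask, g$genome))
    expect_equal(sum(region_overlap_length(w[, c("chrom", "start", "end")],
                                           zones)), 0)
    outside_mask <- complement_regions(mask, g$genome)
    expect_equal(sum(region_overlap_length(w[, c("chrom", "start", "end")],
                                           outside_mask)), 0)
  }
})
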