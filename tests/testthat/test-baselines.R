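# CpG-ratio and island-caller baselines.

test_that("observed/expected CpG ratio worked examples", {
  expect_equal(cpg_obs_exp_ratio("CGCG"), 2.0)
  expect_equal(cpg_obs_exp_ratio("AATT"), 0.0)
  expect_equal(cpg_obs_exp_ratio("ACGT"), 4.0)
  expect_error(cpg_obs_exp_ratio(""), "empty")
  # N bases are excluded from all counts
  expect_equal(cpg_obs_exp_ratio("ACGTN"), 4.0)
})

test_that("obs/exp ratio is scale-invariant on periodic sequence", {
  for (n in c(1, 5, 50, 400)) {
    expect_equal(cpg_obs_exp_ratio(strrep("CG", n)), 2.0)
  }
})

test_that("GC fraction worked examples", {
  expect_equal(gc_fraction("CGCG"), 1.0)
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0.0)
  expect_equal(gc_fraction("ANC"), 0.5)
  expect_error(gc_fraction("NNN"), "all-N")
})

test_that("window scoring by CpG ratio", {
  w <- data.frame(seq = c(strrep("CG", 375), strrep("A", 750)),
                  stringsAsFactors = FALSE)
  out <- score_windows_cpg_ratio(w)
  expect_equal(out$score, c(2.0, 0.0))
})

test_that("Gardiner-Garden & Frommer predicate uses strict inequalities", {
  expect_true(ggf_predicate(strrep("CG", 150)))
  expect_false(ggf_predicate(strrep("AT", 150)))
  expect_false(ggf_predicate(strrep("CG", 100))) # exactly 200 bp: not > 200
})

test_that("running score follows the +17 / -1 convention", {
  contrib <- nmiscan:::.running_contrib(nmiscan:::seq_to_codes("CGAA"))
  expect_equal(sum(contrib), 17 - 1 - 1)
  expect_equal(contrib, c(17, 0, -1, -1))
})

test_that("island scan worked examples", {
  expect_equal(nrow(ucsc_island_scan(strrep("A", 300))), 0)

  calls <- ucsc_island_scan(strrep("CG", 150))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 300)
  expect_equal(calls$gc_fraction, 1.0)
  expect_equal(calls$obs_exp_ratio, 2.0)
  expect_equal(calls$cpg_count, 150)
})

test_that("island calls are invariant to flanking A-runs", {
  core <- strrep("CG", 150)
  plain <- ucsc_island_scan(core)
  flanked <- ucsc_island_scan(paste0(strrep("A", 400), core, strrep("A", 600)))
  expect_equal(nrow(flanked), 1)
  expect_equal(flanked$start, 400)
  expect_equal(flanked$end, 400 + 300)
  expect_equal(flanked$gc_fraction, plain$gc_fraction)
  expect_equal(flanked$obs_exp_ratio, plain$obs_exp_ratio)
  expect_equal(flanked$cpg_count, plain$cpg_count)
})

test_that("every emitted island satisfies all three thresholds", {
  for (seed in 1:4) {
    # CpG-rich patches on an AT-rich background provoke candidates
    s <- nmiscan:::with_seed(seed, {
      paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                   prob = c(0.25, 0.3, 0.3, 0.15)), collapse = "")
    })
    calls <- ucsc_island_scan(s)
    if (nrow(calls) > 0) {
      expect_true(all(calls$length >= 200))
      expect_true(all(calls$gc_fraction >= 0.5))
      expect_true(all(calls$obs_exp_ratio >= 0.6))
      expect_true(all(calls$end - calls$start == calls$length))
      # stats recomputed independently from the emitted coordinates
      for (i in seq_len(nrow(calls))) {
        sub <- substr(s, calls$start[i] + 1, calls$end[i])
        expect_equal(gc_fraction(sub), calls$gc_fraction[i])
        expect_equal(cpg_obs_exp_ratio(sub), calls$obs_exp_ratio[i])
      }
    }
  }
})

test_that("genome-wide island calling attaches chromosome names", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("CG", 150),
                                  c2 = strrep("AT", 200)))
  calls <- ucsc_islands_genome(g)
  expect_equal(calls$chrom, "c1")
  f <- withr::local_tempfile(fileext = ".bed")
  write_islands_bed(calls, f)
  expect_equal(read_bed(f), regions("c1", 0, 300))
})
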