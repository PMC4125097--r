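# Read collapsing, 3' extension, ppm binning, tiling and masking.

test_that("ingest_and_collapse merges by (chrom, start, strand)", {
  reads <- data.frame(
    chrom = "chr1", start = c(100, 100, 100, 250),
    end = c(136, 136, 136, 286), name = ".",
    score = c(1, 1, 2, 1), strand = c("+", "+", "-", "+"))
  out <- ingest_and_collapse(reads)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$occurrences), sum(reads$score))
  plus100 <- out[out$start == 100 & out$strand == "+", ]
  expect_equal(plus100$occurrences, 2)
  minus100 <- out[out$start == 100 & out$strand == "-", ]
  expect_equal(minus100$occurrences, 2)
  expect_warning(ingest_and_collapse(reads[0, ]), "no reads")
  ann <- toy_annotation(1e6)
  bad <- transform(reads, chrom = "chrUn")
  expect_error(ingest_and_collapse(bad, ann), "unknown chromosome")
})

test_that("read_bed validates records and defaults missing scores to 1", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "chr1\t10\t46\tr1\t3\t+",
               "chr1\t20\t56"), f)
  out <- read_bed(f)
  expect_equal(out$score, c(3L, 1L))
  expect_equal(out$strand, c("+", "+"))
  writeLines(c("chr1\t10\t46\tr1\t3\t+", "chr1\tnot\tgood"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("extend_reads extends 3'-ward and clips at chromosome ends", {
  ann <- toy_annotation(1e6)
  a <- data.frame(chrom = "chr1",
                  start = c(1000, 886, 999900),
                  end = c(1036, 1036, 999936),
                  strand = c("+", "-", "+"), occurrences = c(1, 2, 1))
  out <- extend_reads(a, ann, 150)
  expect_equal(out$start, c(1000, 886, 999900))
  expect_equal(out$end, c(1150, 1036, 1e6))   # third clipped to 100 bp
  expect_equal(out$occurrences, a$occurrences)
  # minus-strand read near the origin clips at 0
  b <- data.frame(chrom = "chr1", start = 10, end = 46, strand = "-",
                  occurrences = 1)
  expect_equal(extend_reads(b, ann, 150)$start, 0)
  expect_error(extend_reads(a, ann, 0), "positive")
})

test_that("bin_coverage matches direct arithmetic on a single fragment", {
  ann <- toy_annotation(1e6)
  frag <- data.frame(chrom = "chr1", start = 0, end = 150, strand = "+",
                     occurrences = 1)
  tr <- bin_coverage(frag, ann, bin_size = 20)
  v <- tr$values$chr1
  expect_equal(v[1:7], rep(2e7, 7))   # 20 covered bases x 1e6/1
  expect_equal(v[8], 1e7)             # bases 140-149: 10 covered
  expect_equal(sum(v), 1.5e8)
  expect_true(all(v[-(1:8)] == 0))
})

test_that("coverage conservation and ppm scale-invariance hold", {
  ann <- toy_annotation(1e4)
  frags <- random_fragments(200, 1e4, seed = 31)
  tr <- bin_coverage(frags, ann, 20)
  # conservation: sum of bins = 1e6 * sum(occ * len) / total_occ
  expect_equal(sum(tr$values$chr1),
               1e6 * sum(frags$occurrences * (frags$end - frags$start)) /
                 sum(frags$occurrences))
  # doubling occurrences leaves the ppm track untouched
  frags2 <- transform(frags, occurrences = occurrences * 3L)
  tr2 <- bin_coverage(frags2, ann, 20)
  expect_equal(tr2$values$chr1, tr$values$chr1)
  expect_error(bin_coverage(frags[0, ], ann), "zero total")
})

test_that("bin_coverage equals the per-base brute-force oracle", {
  ann <- toy_annotation(1e4)
  for (seed in c(5, 17)) {
    frags <- random_fragments(300, 1e4, seed = seed)
    tr <- bin_coverage(frags, ann, 20)
    want <- oracle_bin_coverage(frags, 1e4, 20)
    expect_equal(tr$values$chr1, want, tolerance = 1e-12)
  }
})

test_that("make_tile_table emits full tiles with half-open TSS counting", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(99999, 100000, 150000), strand = "+",
                      expression = 8)
  ann <- toy_annotation(25e4, genes)
  tr <- toy_track(rep(2, 25e4 / 20), bin_size = 20, chrom_len = 25e4)
  tiles <- make_tile_table(tr, ann)
  expect_equal(nrow(tiles), 2)               # trailing 50 kb dropped
  expect_equal(tiles$start, c(0, 1e5))
  expect_equal(tiles$gene_count, c(1, 2))    # boundary TSS in 2nd tile
  expect_equal(tiles$signal, rep(2 * 5000, 2))  # uniform coverage
  short <- toy_annotation(5e4)
  trs <- toy_track(rep(1, 2500), chrom_len = 5e4)
  expect_warning(expect_error(make_tile_table(trs, short), "no chromosome"),
                 "shorter")
})

test_that("mask_tiles flags ceil(1%) by control, zero-read by target", {
  mk <- function(signal) {
    structure(data.frame(chrom = "chr1",
                         start = (seq_along(signal) - 1) * 1e5,
                         end = seq_along(signal) * 1e5,
                         signal = signal,
                         gene_count = 0L, mask = "ok"),
              class = c("tile_table", "data.frame"),
              tile_size = 1e5L)
  }
  set.seed(2)
  target <- mk(runif(200, 1, 10))
  control <- mk(runif(200, 1, 10))
  suppressMessages(out <- mask_tiles(target, control))
  expect_equal(sum(grepl("artifact", out$mask)), 2)  # ceil(0.01 * 200)
  flagged <- which(grepl("artifact", out$mask))
  expect_setequal(flagged, order(-control$signal)[1:2])
  # all-zero control: no artifact flags; zero-read flags from target
  target2 <- mk(c(0, runif(199, 1, 10)))
  suppressMessages(out2 <- mask_tiles(target2, mk(rep(0, 200))))
  expect_equal(sum(grepl("artifact", out2$mask)), 0)
  expect_equal(which(out2$mask == "zero_reads"), 1L)
  # adversarial control: the huge tile is flagged regardless of target
  ctrl3 <- mk(c(rep(1, 199), 1e6))
  suppressMessages(out3 <- mask_tiles(target, ctrl3))
  expect_true(grepl("artifact", out3$mask[200]))
  expect_error(mask_tiles(target, mk(runif(150))), "grid")
})

test_that("tile signal equals a direct oracle recomputation", {
  set.seed(9)
  v <- rexp(3e5 / 20)
  ann <- toy_annotation(3e5)
  tr <- toy_track(v, chrom_len = 3e5)
  tiles <- make_tile_table(tr, ann)
  expect_equal(tiles$signal, oracle_tile_signal(v, 20, 1e5, 3))
})
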