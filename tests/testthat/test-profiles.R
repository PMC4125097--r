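# TSS matrices, flank normalization, summaries, clustering, quintiles.

spike_track <- function(spike_bin, value = 10, n_bins = 1000) {
  v <- rep(1, n_bins)
  v[spike_bin + 1L] <- value   # spike_bin is 0-based
  toy_track(v, chrom_len = n_bins * 20)
}

test_that("tss_matrix orients rows by transcription strand", {
  # plus-strand gene at 10000, spike 100 bp downstream (genomic 10100)
  genes <- data.frame(gene_id = "g+", chrom = "chr1", tss = 10000,
                      strand = "+", expression = 8)
  ann <- toy_annotation(2e4, genes)
  tr <- spike_track(10100 %/% 20)
  m <- tss_matrix(tr, ann)
  expect_equal(ncol(m$values), 400)
  expect_equal(unname(which(m$values[1, ] == 10)), 206)  # 0-based bin 205
  # minus-strand gene, same genomic spike now 100 bp 5' of the TSS in
  # genomic terms -> upstream after the orientation flip
  genes$strand <- "-"
  annm <- toy_annotation(2e4, genes)
  mm <- tss_matrix(tr, annm)
  expect_equal(unname(which(mm$values[1, ] == 10)), 195)  # 0-based 194
  # flip property: reversing the strand mirrors the row exactly
  expect_equal(mm$values[1, ], rev(m$values[1, ]))
})

test_that("windows truncated by chromosome ends are missing, not zero", {
  genes <- data.frame(gene_id = "edge", chrom = "chr1", tss = 1000,
                      strand = "+", expression = 8)
  ann <- toy_annotation(2e5, genes)
  tr <- toy_track(rep(1, 1e4), chrom_len = 2e5)
  m <- tss_matrix(tr, ann)
  expect_true(all(is.na(m$values[1, 1:150])))   # 3000 bp off-chromosome
  expect_true(all(m$values[1, 151:400] == 1))
  bad <- genome_annotation(data.frame(name = "chr9", length = 2e5),
                           transform(genes, chrom = "chr9"))
  expect_error(tss_matrix(tr, bad), "unknown chromosome")
})

test_that("anchor_matrix agrees with tss_matrix and a window oracle", {
  set.seed(21)
  v <- rexp(2000)
  tr <- toy_track(v, chrom_len = 4e4)
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 20000,
                      strand = "+", expression = 8)
  ann <- toy_annotation(4e4, genes)
  m <- tss_matrix(tr, ann)
  am <- anchor_matrix(tr, data.frame(chrom = "chr1", midpoint = 20000),
                      span = 8000)
  expect_equal(unname(am$values[1, ]), unname(m$values[1, ]))
  # brute-force window oracle on random anchors
  mids <- c(8000, 15000, 31000)
  am2 <- anchor_matrix(tr, data.frame(chrom = "chr1", midpoint = mids),
                       span = 8000)
  for (i in seq_along(mids)) {
    b0 <- (mids[i] - 4000) %/% 20
    expect_equal(unname(am2$values[i, ]), v[(b0 + 1):(b0 + 400)])
  }
  expect_error(anchor_matrix(tr, data.frame(chrom = character(),
                                            midpoint = numeric())),
               "empty")
  # single anchor over uniform coverage is flat
  flat <- anchor_matrix(toy_track(rep(3, 2000), chrom_len = 4e4),
                        data.frame(chrom = "chr1", midpoint = 20000))
  expect_true(all(flat$values == 3))
})

test_that("flank_normalize divides by the upstream flank then log2s", {
  v <- rep(2, 400); v[250] <- 8
  m <- new_m <- structure(list(values = matrix(v, 1), gene_ids = "g",
                               bin_size = 20L, flank = 4000, units = "ppm",
                               oriented = TRUE), class = "tss_matrix")
  out <- flank_normalize(m)
  expect_equal(unname(out$values[1, 250]), 2)   # log2(8/2)
  expect_equal(unname(out$values[1, 1]), 0)     # flat elsewhere
  # flat row -> all zeros
  mflat <- m; mflat$values <- matrix(rep(4, 400), 1)
  expect_true(all(flank_normalize(mflat)$values == 0))
  # idempotence on the ratio scale
  r1 <- flank_normalize(m, log = FALSE)
  r2 <- flank_normalize(r1, log = FALSE)
  expect_equal(r2$values, r1$values)
  # sub-pseudocount flank flags the row
  mlow <- m; mlow$values <- matrix(rep(1e-4, 400), 1)
  suppressMessages(low <- flank_normalize(mlow))
  expect_true(all(is.na(low$values)))
  expect_equal(attr(low, "flagged"), "g")
  expect_error(flank_normalize(m, flank_window = c(-100, -100)), "empty")
  # the alternative grouped-average window is honored
  alt <- flank_normalize(m, flank_window = c(-2500, -1500))
  expect_equal(unname(alt$values[1, 250]), 2)
})

test_that("meta_average is the column mean over the subset", {
  set.seed(4)
  vals <- matrix(rexp(5 * 400), 5)
  m <- structure(list(values = vals, gene_ids = paste0("g", 1:5),
                      bin_size = 20L, flank = 4000, units = "ppm",
                      oriented = TRUE), class = "tss_matrix")
  expect_equal(meta_average(m, "g2"), vals[2, ])
  expect_equal(meta_average(m), colMeans(vals))
  two <- structure(m, class = "tss_matrix")
  two$values <- rbind(rep(0, 400), rep(2, 400))
  two$gene_ids <- c("a", "b")
  expect_true(all(meta_average(two) == 1))
  expect_error(meta_average(m, character(0)), "empty")
  # normalize-then-average equals average-then-normalize when flank
  # means agree
  eq <- m
  eq$values <- rbind(vals[1, ], vals[1, c(2:400, 1)])
  eq$gene_ids <- c("a", "b")
  fm <- rowMeans(eq$values[, 1:100])
  eq$values <- eq$values / fm * 2   # force equal flank means
  path1 <- meta_average(flank_normalize(eq, log = FALSE))
  path2 <- as.numeric(flank_normalize(
    profile_as_matrix(meta_average(eq), eq), log = FALSE)$values)
  expect_equal(path1, path2, tolerance = 1e-12)
})

test_that("promoter_summary is the -600..+600 window mean", {
  v <- rep(0, 400)
  m <- structure(list(values = matrix(v, 1), gene_ids = "g",
                      bin_size = 20L, flank = 4000, units = "ppm",
                      oriented = TRUE), class = "tss_matrix")
  m$values <- matrix(rep(3.5, 400), 1)
  expect_equal(unname(promoter_summary(m)), 3.5)
  # spike outside the window contributes nothing
  v2 <- rep(0, 400); v2[100] <- 50
  m$values <- matrix(v2, 1)
  expect_equal(unname(promoter_summary(m)), 0)
  # random row equals the direct 60-bin mean (bins 171..230)
  set.seed(8)
  v3 <- rexp(400)
  m$values <- matrix(v3, 1)
  expect_equal(unname(promoter_summary(m)), mean(v3[171:230]))
  # all-missing window -> NA
  v4 <- rep(1, 400); v4[171:230] <- NA
  m$values <- matrix(v4, 1)
  expect_true(is.na(promoter_summary(m)))
})

test_that("cluster_and_merge recovers planted shapes and merges twins", {
  set.seed(10)
  peak <- exp(-((seq_len(400) - 200)^2) / 50)      # promoter-like peak
  block <- c(rep(0, 100), rep(0.8, 200), rep(0, 100))  # broad block
  vals <- rbind(
    t(replicate(500, peak + rnorm(400, sd = 0.05))),
    t(replicate(500, block + rnorm(400, sd = 0.05))))
  m <- structure(list(values = vals, gene_ids = paste0("g", 1:1000),
                      bin_size = 20L, flank = 4000, units = "ppm",
                      oriented = TRUE), class = "tss_matrix")
  lab <- cluster_and_merge(m, k = 4, seed = 5)
  # two planted shapes, k = 4: near-duplicate centroids merge; purity
  truthlab <- rep(1:2, each = 500)
  tab <- table(lab, truthlab)
  purity <- sum(apply(tab, 1, max)) / 1000
  expect_gte(purity, 0.95)
  expect_identical(lab, cluster_and_merge(m, k = 4, seed = 5))
  # identical rows collapse to one effective cluster
  same <- m
  same$values <- matrix(rep(peak, 40), 40, byrow = TRUE)
  same$gene_ids <- paste0("s", 1:40)
  lab2 <- cluster_and_merge(same, k = 4, seed = 5)
  expect_equal(length(unique(lab2)), 1)
  expect_error(cluster_and_merge(same, k = 50, seed = 1), "exceeds")
})

test_that("running_window is a centered shrinking-edge moving mean", {
  expect_equal(running_window(1:10, 1), as.numeric(1:10))
  expect_equal(running_window(rep(7, 20), 5), rep(7, 20))
  expect_equal(running_window(1:10, 3)[5], 5)
  expect_equal(running_window(1:10, 3)[1], 1.5)  # shrunk edge window
  expect_error(running_window(1:5, 6), "exceeds")
})

test_that("expression_quintiles groups evenly and tracks planted trends", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                      tss = seq(1000, by = 1000, length.out = 100),
                      strand = "+", expression = seq(1, 10, length.out = 100))
  ann <- toy_annotation(2e6, genes)
  s <- stats::setNames(rep(1, 100), genes$gene_id)
  q <- expression_quintiles(s, ann)
  expect_equal(q$n, rep(20, 5))
  expect_true(all(q$median == 1) && all(q$q1 == 1) && all(q$sd == 0))
  # planted monotone coupling: summary = expression + noise
  set.seed(12)
  s2 <- stats::setNames(genes$expression + rnorm(100, sd = 0.3),
                        genes$gene_id)
  q2 <- expression_quintiles(s2, ann)
  expect_true(all(diff(q2$median) > 0))
  expect_error(expression_quintiles(s[1:3], ann), "fewer")
})
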