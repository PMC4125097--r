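# Synthetic genome generation, kinetic truth assignment, read sampling.

test_that("make_genome handles the empty case and is deterministic", {
  cfg0 <- sim_config(seed = 1, n_genes = 0, n_chroms = 1,
                     chrom_length = 2e6)
  ann <- make_genome(cfg0)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$chromosomes), 1)
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 4e6,
                    n_genes = 400)
  a1 <- make_genome(cfg)
  a2 <- make_genome(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(attr(a1, "units"), attr(a2, "units"))
  expect_error(make_genome(sim_config(seed = 1, chrom_length = 5e4)),
               "100 kb")
})

test_that("gene-desert fraction and density extremes match the config", {
  cfg <- sim_config(seed = 7, n_chroms = 2, chrom_length = 8e6,
                    n_genes = 1200, desert_frac = 0.2)
  ann <- make_genome(cfg)
  # brute-force window census over the emitted annotation
  unit <- 1e5
  empties <- 0; total <- 0
  runs <- integer(0)
  for (i in seq_len(nrow(ann$chromosomes))) {
    ch <- ann$chromosomes$name[i]
    n_units <- floor(ann$chromosomes$length[i] / unit)
    tss <- ann$genes$tss[ann$genes$chrom == ch]
    cnt <- tabulate(floor(tss / unit) + 1L, nbins = n_units)
    empties <- empties + sum(cnt == 0)
    total <- total + n_units
    r <- rle(cnt == 0)
    runs <- c(runs, r$lengths[r$values])
  }
  expect_lt(abs(empties / total - cfg$desert_frac), 0.03)
  # at least one contiguous >= 500 kb zero-gene region
  expect_gte(max(runs), 5L)
  # some 1-Mb region reaches >= 5x the genome-mean gene density
  mean_density <- nrow(ann$genes) / sum(ann$chromosomes$length)
  best <- 0
  for (i in seq_len(nrow(ann$chromosomes))) {
    ch <- ann$chromosomes$name[i]
    tss <- sort(ann$genes$tss[ann$genes$chrom == ch])
    if (length(tss) == 0) next
    for (s in seq(0, ann$chromosomes$length[i] - 1e6, by = unit)) {
      best <- max(best, sum(tss >= s & tss < s + 1e6) / 1e6)
    }
  }
  expect_gte(best / mean_density, 5)
})

test_that("assign_kinetics couples promoter rate to expression", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 3e6,
                    n_genes = 300)
  ann <- make_genome(cfg)
  truth <- assign_kinetics(ann, cfg)
  expect_setequal(unique(truth$class),
                  c("hot_promoter", "cold_block", "background", "artifact"))
  prom <- truth[truth$class == "hot_promoter", ]
  genes <- ann$genes[match(sub("^prom_", "", prom$locus_id),
                           ann$genes$gene_id), ]
  # deterministic monotone coupling: e1 < e2 implies k1 <= k2
  ord <- order(genes$expression)
  expect_true(all(diff(prom$k[ord]) >= 0))
  expect_gte(cor(genes$expression, prom$k, method = "spearman"), 0.9)
  # promoters sit above background, cold blocks at ~0
  expect_true(all(prom$k > cfg$k_background))
  expect_true(all(truth$k[truth$class == "cold_block"] <= 1e-9))
  # one promoter per expressed gene, ~1.2 kb wide, centered on the TSS
  expressed <- ann$genes[ann$genes$expression >= cfg$expressed_threshold, ]
  expect_equal(nrow(prom), nrow(expressed))
  expect_true(all(abs((prom$end - prom$start) - 1200) <= 1))
})

test_that("MEF mode shrinks promoter rate dispersion and adds cold blocks", {
  base <- list(seed = 3, n_chroms = 1, chrom_length = 3e6, n_genes = 300)
  cfg_es <- do.call(sim_config, c(base, mode = "ES"))
  cfg_mef <- do.call(sim_config, c(base, mode = "MEF"))
  ann <- make_genome(cfg_es)
  t_es <- assign_kinetics(ann, cfg_es)
  t_mef <- assign_kinetics(ann, cfg_mef)
  k_es <- t_es$k[t_es$class == "hot_promoter"]
  k_mef <- t_mef$k[t_mef$class == "hot_promoter"]
  expect_lt(var(k_mef), var(k_es))
  expect_gt(sum(t_mef$class == "cold_block"),
            sum(t_es$class == "cold_block"))
})

test_that("sample_reads is seeded, conserves depth, and respects zeros", {
  ann <- toy_annotation(chrom_len = 1e6)
  truth <- data.frame(
    locus_id = c("on", "off"), chrom = "chr1",
    start = c(0, 5e5), end = c(5e5, 1e6),
    occupancy = c(1, 1), k = c(1, 0), rep_offset = 6,
    class = c("background", "background"), nonspec = 0)
  signal <- data.frame(locus_id = c("on", "off"), mean_tagged = c(0.5, 0),
                       signal = c(0.5, 0))
  cfg <- sim_config(seed = 5, depth = 1e5, n_chroms = 1,
                    chrom_length = 1e6, n_genes = 0)
  r1 <- sample_reads(signal, truth, cfg, ann, "t3")
  r2 <- sample_reads(signal, truth, cfg, ann, "t3")
  expect_identical(r1, r2)
  # zero-signal, zero-nonspec locus emits nothing (minus-strand reads may
  # protrude up to one fragment length past the live locus boundary)
  expect_true(all(r1$start < 5e5 + 150))
  # Poisson total within 3 sqrt(depth) of the configured depth
  expect_lt(abs(nrow(r1) - cfg$depth), 3 * sqrt(cfg$depth))
  # all-zero signal is an explicit error
  signal0 <- data.frame(locus_id = c("on", "off"), signal = c(0, 0))
  expect_error(sample_reads(signal0, truth, cfg, ann), "zero")
})

test_that("written simulator outputs round-trip and carry the seed", {
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 1e6,
                    n_genes = 40, depth = 2e4)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(file.exists(paths$annotation))
  header <- readLines(paths$reads_t3, n = 1)
  expect_match(header, "seed: 9")
  back <- read_bed(paths$reads_t3)
  expect_equal(nrow(back), nrow(sim$reads$t3))
  expect_equal(back$start, sim$reads$t3$start)
  ann2 <- read_annotation(paths$annotation)
  expect_equal(ann2$genes$tss, sim$annotation$genes$tss)
  expect_equal(ann2$chromosomes$length, sim$annotation$chromosomes$length)
})
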