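# Synthetic genome annotation: chromosomes plus genes with TSS, strand and
# expression. The layout deliberately mixes gene-rich blocks with multi-
# hundred-kb gene deserts, the two territory types whose contrast drives
# every density analysis downstream.

#' Construct a genome annotation
#'
#' The coordinate frame for the whole pipeline: chromosome sizes plus a
#' gene table (id, chromosome, 0-based TSS, strand, expression in log2
#' intensity units). Validates uniqueness of gene ids and that every gene
#' lies on a known chromosome within bounds.
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand` (`"+"`/`"-"`), `expression`. May have zero rows.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes) {
  chromosomes <- as.data.frame(chromosomes)
  genes <- as.data.frame(genes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        expression = numeric())
  }
  stopifnot(all(c("gene_id", "chrom", "tss", "strand", "expression")
                %in% names(genes)))
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (nrow(genes) > 0) {
    if (!all(genes$chrom %in% chromosomes$name)) {
      bad <- setdiff(unique(genes$chrom), chromosomes$name)
      stop("gene chromosome(s) not in genome: ", paste(bad, collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
    if (any(genes$tss < 0 | genes$tss >= len)) {
      stop("TSS outside chromosome bounds")
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %.3g bp total, %d genes\n",
              nrow(x$chromosomes), sum(x$chromosomes$length),
              nrow(x$genes)))
  invisible(x)
}

chrom_lengths <- function(annotation) {
  stats::setNames(annotation$chromosomes$length, annotation$chromosomes$name)
}

# Segment a chromosome into 100-kb units labelled desert / rich / normal.
# Deserts are contiguous runs of >= 5 units (>= 500 kb); rich blocks are
# contiguous runs of ~10 units. Returns a character vector per unit.
segment_units <- function(n_units, desert_frac, rich_frac) {
  lab <- rep("normal", n_units)
  place_runs <- function(lab, n_target, run_len, what) {
    placed <- 0
    guard <- 0
    while (placed < n_target && guard < 1000) {
      guard <- guard + 1
      len <- min(run_len, n_target - placed)
      if (len < 1) break
      cand <- which(lab == "normal")
      starts <- cand[vapply(cand, function(s) {
        s + len - 1 <= n_units && all(lab[s:(s + len - 1)] == "normal")
      }, logical(1))]
      if (length(starts) == 0) break
      s <- sample(starts, 1)
      lab[s:(s + len - 1)] <- what
      placed <- placed + len
    }
    lab
  }
  n_desert <- round(desert_frac * n_units)
  n_rich <- round(rich_frac * n_units)
  # desert runs of 8 units (800 kb), rich blocks of 10 units (1 Mb)
  lab <- place_runs(lab, n_desert, 8L, "desert")
  lab <- place_runs(lab, n_rich, 10L, "rich")
  lab
}

#' Generate a synthetic genome annotation
#'
#' Builds chromosomes segmented into gene deserts (contiguous, >= 500 kb,
#' zero genes), gene-rich blocks (placement weight `rich_weight` per
#' 100-kb unit) and normal territory, then places genes with random
#' strand and bimodal (silent vs expressed) log2-intensity expression.
#' Deterministic for a given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()]; gene territory labels are kept in
#'   `attr(, "units")` (per-100-kb unit types per chromosome).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  unit <- 100000L
  if (config$chrom_length < unit) {
    stop("chromosome length must be at least 100 kb")
  }
  n_units <- floor(config$chrom_length / unit)
  # every gene needs somewhere non-desert to live
  if (config$n_genes > 0 && (1 - config$desert_frac) * n_units < 1) {
    stop("chromosome too small to host the requested genes")
  }
  set.seed(derive_seed(config$seed, "make_genome"))
  chroms <- data.frame(name = paste0("chr", seq_len(config$n_chroms)),
                       length = rep(config$chrom_length, config$n_chroms))
  units <- lapply(seq_len(config$n_chroms), function(i) {
    segment_units(n_units, config$desert_frac, config$rich_frac)
  })
  names(units) <- chroms$name

  genes <- NULL
  if (config$n_genes > 0) {
    ulab <- unlist(units, use.names = FALSE)
    uchrom <- rep(chroms$name, each = n_units)
    ustart <- rep((seq_len(n_units) - 1L) * unit, times = config$n_chroms)
    w <- ifelse(ulab == "desert", 0,
         ifelse(ulab == "rich", config$rich_weight, 1))
    if (sum(w) == 0) stop("no non-desert territory available for genes")
    pick <- sample.int(length(w), config$n_genes, replace = TRUE,
                       prob = w / sum(w))
    pos <- ustart[pick] + sample.int(unit, config$n_genes, replace = TRUE) - 1L
    silent <- stats::runif(config$n_genes) < config$expr_silent_frac
    expr <- ifelse(silent,
                   stats::rnorm(config$n_genes, config$expr_means[1],
                                config$expr_sds[1]),
                   stats::rnorm(config$n_genes, config$expr_means[2],
                                config$expr_sds[2]))
    ord <- order(match(uchrom[pick], chroms$name), pos)
    genes <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
      chrom = uchrom[pick][ord],
      tss = pos[ord],
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      expression = expr[ord])
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        expression = numeric())
  }
  ann <- genome_annotation(chroms, genes)
  attr(ann, "units") <- units
  attr(ann, "unit_size") <- unit
  attr(ann, "seed") <- config$seed
  ann
}

#' Write / read a gene annotation as TSV
#'
#' Five columns (gene_id, chrom, tss, strand, expression) plus a
#' `# chrom_sizes:` header line carrying chromosome lengths and, when the
#' annotation came from the simulator, the generating seed.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a [genome_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  sizes <- paste(sprintf("%s=%d", annotation$chromosomes$name,
                         as.integer(annotation$chromosomes$length)),
                 collapse = ",")
  writeLines(sprintf("# chrom_sizes: %s", sizes), con)
  seed <- attr(annotation, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(annotation$genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  header <- readLines(path, n = 5)
  szline <- grep("^# chrom_sizes:", header, value = TRUE)
  if (length(szline) == 0) stop("annotation file lacks '# chrom_sizes:' header")
  pairs <- strsplit(sub("^# chrom_sizes:\\s*", "", szline[1]), ",")[[1]]
  kv <- strsplit(pairs, "=")
  chroms <- data.frame(name = vapply(kv, `[`, "", 1),
                       length = as.numeric(vapply(kv, `[`, "", 2)))
  genes <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  genome_annotation(chroms, genes)
}
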