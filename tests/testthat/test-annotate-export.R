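calls_df <- function(chrom, start, end, q, significant = TRUE) {
  data.frame(chrom = chrom, start = start, end = end,
             id = seq_along(start), distance = NA_real_,
             raw_count = 100, rpm = 10, signal = 10,
             z = 3, p = q / 2, q = q, is_cis = TRUE,
             significant = significant)
}

gene_gr <- function(chrom, start, end, strand, name) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                              strand = strand)
  g$gene_name <- name
  g
}

test_that("genes are reported through strand-aware proximity windows", {
  genes <- gene_gr("c1", 100000, 105000, "+", "geneA")
  near <- annotate_genes(calls_df("c1", 60000, 64000, 0.01), genes)
  expect_equal(near$gene, "geneA")  # call inside [50000, 110000)
  far <- annotate_genes(calls_df("c1", 40000, 44000, 0.01), genes)
  expect_equal(nrow(far), 0L)
  # on the minus strand the 50-kb window lies to the right of the gene
  genes_m <- gene_gr("c1", 100000, 105000, "-", "geneB")
  right <- annotate_genes(calls_df("c1", 140000, 144000, 0.01), genes_m)
  expect_equal(right$gene, "geneB")
  left <- annotate_genes(calls_df("c1", 60000, 64000, 0.01), genes_m)
  expect_equal(nrow(left), 0L)
})

test_that("zero-width windows still report calls inside the gene body", {
  genes <- gene_gr("c1", 100000, 105000, "+", "geneA")
  hit <- annotate_genes(calls_df("c1", 101000, 102000, 0.02), genes,
                        upstream_bp = 0, downstream_bp = 0)
  expect_equal(hit$gene, "geneA")
})

test_that("each gene is reported once with its best supporting call", {
  genes <- gene_gr("c1", 100000, 105000, "+", "geneA")
  calls <- calls_df("c1", c(60000, 101000, 108000),
                    c(64000, 102000, 109000), c(0.04, 0.001, 0.02))
  hit <- annotate_genes(calls, genes)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$best_q, 0.001)
  expect_equal(hit$n_calls, 3L)
  # only significant calls count
  calls$significant <- c(TRUE, FALSE, TRUE)
  hit2 <- annotate_genes(calls, genes)
  expect_equal(hit2$best_q, 0.02)
})

test_that("widening the proximity window never removes a gene", {
  set.seed(77)
  genes <- gene_gr("c1", seq(0, 9e5, 1e5), seq(0, 9e5, 1e5) + 20000,
                   sample(c("+", "-"), 10, TRUE), paste0("g", 1:10))
  starts <- seq(5000, 9.5e5, 5e4)
  calls <- calls_df("c1", starts, starts + 3000,
                    runif(length(starts), 0.001, 0.04))
  small <- annotate_genes(calls, genes, upstream_bp = 1000,
                          downstream_bp = 0)
  big <- annotate_genes(calls, genes, upstream_bp = 50000,
                        downstream_bp = 5000)
  expect_true(all(small$gene %in% big$gene))
})

test_that("gene models load from GTF and BED", {
  skip_if_not_installed("rtracklayer")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("c1\ttest\texon\t101\t200\t.\t+\t.\t",
           "gene_id \"G1\"; gene_name \"Alpha\";"),
    paste0("c1\ttest\texon\t301\t400\t.\t+\t.\t",
           "gene_id \"G1\"; gene_name \"Alpha\";"),
    paste0("c2\ttest\texon\t501\t700\t.\t-\t.\t",
           "gene_id \"G2\"; gene_name \"Beta\";")), gtf)
  genes <- read_gene_models(gtf)
  expect_setequal(genes$gene_name, c("Alpha", "Beta"))
  alpha <- genes[genes$gene_name == "Alpha"]
  expect_equal(GenomicRanges::start(alpha), 101L)
  expect_equal(GenomicRanges::end(alpha), 400L)

  bed <- tempfile(fileext = ".bed")
  writeLines("c1\t100\t200\tGamma\t0\t+", bed)
  genes_b <- read_gene_models(bed)
  expect_equal(genes_b$gene_name, "Gamma")
  expect_equal(GenomicRanges::start(genes_b), 101L)
})

test_that("bedGraph export follows the UCSC dialect", {
  fm <- tiny_fm()
  sig <- fm
  sig$region_id <- fm$fragment_id
  sig$raw_count <- c(0L, 500L, 2L)
  sig$rpm <- NA_real_
  sig$norm_rpm <- c(0, 250, 17.5)
  path <- tempfile(fileext = ".bedGraph")
  export_bedgraph(sig, path, value = "norm_rpm", name = "demo")
  lines <- readLines(path)
  expect_equal(lines[1], "track type=bedGraph name=\"demo\"")
  expect_equal(lines[2], "chrT\t3\t13\t250")
  expect_equal(lines[3], "chrT\t13\t21\t17.5")
  expect_equal(length(lines), 3L)  # zero-valued fragment omitted
})

test_that("empty call sets export a header-only bedGraph", {
  path <- tempfile(fileext = ".bedGraph")
  export_bedgraph(calls_df("c1", 0, 100, 0.5)[integer(0), ], path,
                  value = "signal")
  expect_equal(length(readLines(path)), 1L)
})

test_that("overlapping regions are rejected unless allowed", {
  df <- calls_df("c1", c(0, 500), c(1000, 1500), c(0.1, 0.1))
  expect_error(export_bedgraph(df, tempfile(), value = "signal"),
               "overlap")
  p <- tempfile()
  export_bedgraph(df, p, value = "signal", allow_overlap = TRUE)
  expect_equal(length(readLines(p)), 3L)
})

test_that("bedGraph re-parses to the exported regions and values", {
  skip_if_not_installed("rtracklayer")
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 601L
  cfg$n_reads <- 5e4
  sim <- simulate_3cseq(cfg, world$fm)
  sig <- sim_signals(sim$reads, world$fm, cfg$vp)
  path <- tempfile(fileext = ".bedGraph")
  export_bedgraph(sig, path, value = "norm_rpm")
  back <- rtracklayer::import(path, format = "bedGraph")
  keep <- sig[sig$norm_rpm != 0]
  expect_equal(length(back), length(keep))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(keep))
  expect_equal(back$score, signif(keep$norm_rpm, 6), tolerance = 1e-6)
})

test_that("text export round-trips q to six significant digits", {
  calls <- calls_df("c1", c(0, 4000, 8000), c(4000, 8000, 12000),
                    c(0.0123456789, 0.5, 1e-7))
  path <- tempfile(fileext = ".tsv")
  export_text(calls, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4L)  # header + 3 rows
  back <- read.delim(path)
  expect_equal(back$q, signif(calls$q, 6))
  expect_equal(back$start, calls$start)
  # empty input still writes the header
  export_text(calls[integer(0), ], path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("bedGraph and TSV exports carry identical region-value pairs", {
  calls <- calls_df("c1", c(0, 4000), c(4000, 8000), c(0.01, 0.02))
  bg <- tempfile(); tsv <- tempfile()
  export_bedgraph(calls, bg, value = "signal")
  export_text(calls, tsv)
  back_tsv <- read.delim(tsv)
  back_bg <- read.delim(bg, skip = 1, header = FALSE,
                        col.names = c("chrom", "start", "end", "value"))
  expect_equal(back_bg[, c("chrom", "start", "end")],
               back_tsv[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(back_bg$value, signif(back_tsv$signal, 6))
})

test_that("domainogram has 29 rows and exposes a planted interaction", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 602L
  # a strong 10-kb interaction 115-125 kb downstream of the viewpoint
  vmid <- mean(c(GenomicRanges::start(cfg$vp), GenomicRanges::end(cfg$vp)))
  spike_lo <- vmid + 115000
  spike_hi <- vmid + 125000
  hit <- which(GenomicRanges::start(world$fm) <= spike_hi &
                 GenomicRanges::end(world$fm) >= spike_lo &
                 as.character(GenomicRanges::seqnames(world$fm)) == "chr1")
  cfg$spikes <- data.frame(fragment_id = world$fm$fragment_id[hit],
                           fold = 10)
  sim <- simulate_3cseq(cfg, world$fm)
  set.seed(1)
  mat <- domainogram_matrix(sim$reads, cfg$vp, world$sizes, span_bp = 5e5)
  expect_equal(nrow(mat), 29L)
  expect_equal(rownames(mat), as.character(seq(2000, 30000, 1000)))
  pos <- as.numeric(colnames(mat))
  spike_cols <- which(pos >= spike_lo & pos <= spike_hi)
  # the spiked locus is called across (nearly) all window sizes
  frac_called <- mean(apply(mat[, spike_cols, drop = FALSE] <= 0.05, 1,
                            any), na.rm = TRUE)
  expect_gt(frac_called, 0.8)
  path <- tempfile(fileext = ".tsv")
  export_domainogram(mat, path)
  exported <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(exported), 29L)
  expect_true(all(exported[, -1] <= 10, na.rm = TRUE))
})

test_that("a null domainogram shows no persistent low-q column", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 603L
  sim <- simulate_3cseq(cfg, world$fm)
  set.seed(1)
  mat <- domainogram_matrix(sim$reads, cfg$vp, world$sizes, span_bp = 5e5)
  persistent <- colSums(mat <= 0.01, na.rm = TRUE) >= 25
  expect_equal(sum(persistent), 0L)
})
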