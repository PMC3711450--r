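#' Configuration for synthetic 3C-seq data
#'
#' Describes a generative model of a viewpoint-anchored 3C-seq library:
#' cis reads land on fragments with probability proportional to a shifted
#' power-law decay in distance, `(1 + |d| / d0)^-gamma`, optionally
#' multiplied by per-fragment spike folds (the planted true interactions);
#' a `trans_fraction` of reads falls uniformly on trans-chromosome
#' fragments (random ligation); a read's 5' end abuts a restriction-site
#' boundary with probability `informative_fraction`, else it starts
#' uniformly inside its fragment.
#'
#' Defaults describe a small but realistic desk-scale experiment: two 5-Mb
#' chromosomes, HindIII digestion, a viewpoint mid-chromosome 1,
#' `gamma = 1.2`, `d0 = 10` kb, 5% trans reads, 90% informative reads and
#' a 200,000-read library.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param site Restriction enzyme recognition site (IUPAC).
#' @param vp Viewpoint `GRanges`; default is a 4-kb region centred on
#'   chromosome 1.
#' @param n_reads Number of reads to simulate.
#' @param gamma Distance-decay exponent (> 0).
#' @param d0 Decay distance scale (bp).
#' @param spikes `data.frame(fragment_id, fold)` of planted interactions;
#'   `NULL` for none.
#' @param trans_fraction Probability a read is trans, in \[0, 1).
#' @param informative_fraction Probability a read's 5' end sits on a
#'   fragment boundary.
#' @param read_length Read length in bp (reads are clipped to their
#'   fragment).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                              site = "AAGCTT",
                              vp = NULL,
                              n_reads = 2e5,
                              gamma = 1.2,
                              d0 = 1e4,
                              spikes = NULL,
                              trans_fraction = 0.05,
                              informative_fraction = 0.9,
                              read_length = 50L) {
  stopifnot(gamma > 0, trans_fraction >= 0, trans_fraction < 1,
            informative_fraction >= 0, informative_fraction <= 1,
            n_reads >= 1)
  if (is.null(vp)) {
    mid <- floor(chrom_lengths[[1L]] / 2)
    vp <- viewpoint(names(chrom_lengths)[1L], mid - 2000, mid + 2000,
                    name = "sim_viewpoint")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 site = site, vp = vp, n_reads = n_reads, gamma = gamma,
                 d0 = d0, spikes = spikes, trans_fraction = trans_fraction,
                 informative_fraction = informative_fraction,
                 read_length = as.integer(read_length)),
            class = "simulation_config")
}

#' Simulate a random genome
#'
#' I.i.d. uniform A/C/G/T sequence per chromosome, reproducible from the
#' configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @param path Optional FASTA output path.
#' @return A named `DNAStringSet` (written to `path` if given).
#' @export
simulate_genome <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  seqs <- vapply(cfg$chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(cfg$chrom_lengths)
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path)
  genome
}

#' Default spike set for a fragment map
#'
#' Picks 20 fragments — the nearest fragment to each of ten distances
#' 50 kb ... 500 kb on each side of the viewpoint — and assigns them a
#' uniform fold, emulating a band of true contacts at enhancer-promoter
#' distances.
#'
#' @param fm Fragment map.
#' @param vp Viewpoint `GRanges`.
#' @param fold Spike fold (default 10).
#' @param distances Target distances (bp) on each side.
#' @return `data.frame(fragment_id, fold)`.
#' @export
default_spikes <- function(fm, vp, fold = 10,
                           distances = seq(5e4, 5e5, by = 5e4)) {
  d <- region_distance(fm, vp)
  ids <- unlist(lapply(c(-1, 1) , function(s) {
    vapply(distances, function(dd) {
      fm$fragment_id[which.min(abs(d - s * dd))]
    }, 0L)
  }))
  data.frame(fragment_id = unique(ids), fold = fold)
}

# per-fragment sampling weights and ground-truth proportions
simulation_weights <- function(cfg, fm) {
  d <- region_distance(fm, cfg$vp)
  is_cis <- !is.na(d)
  w <- numeric(length(fm))
  w[is_cis] <- (1 + abs(d[is_cis]) / cfg$d0)^(-cfg$gamma)
  spike_fold <- rep(1, length(fm))
  if (!is.null(cfg$spikes) && nrow(cfg$spikes) > 0L) {
    idx <- match(cfg$spikes$fragment_id, fm$fragment_id)
    if (anyNA(idx))
      stop("spike fragment id absent from the fragment map: ",
           cfg$spikes$fragment_id[which(is.na(idx))[1L]])
    spike_fold[idx] <- cfg$spikes$fold
    w <- w * spike_fold
  }
  cis_p <- w / sum(w) * (1 - cfg$trans_fraction)
  p <- cis_p
  if (any(!is_cis) && cfg$trans_fraction > 0)
    p[!is_cis] <- cfg$trans_fraction / sum(!is_cis)
  data.frame(fragment_id = fm$fragment_id, expected_prop = p,
             spike_fold = spike_fold, is_cis = is_cis)
}

#' Simulate a 3C-seq library over a fragment map
#'
#' Draws `n_reads` fragment assignments from the generative model of
#' [simulation_config()] and places each read inside its fragment: 5' end
#' on a fragment boundary with probability `informative_fraction` (plus
#' strand at the left boundary, minus strand at the right), else uniform
#' within the fragment; strand uniform. Returns the reads in memory and,
#' optionally, writes a coordinate-sorted indexed BAM, a ground-truth TSV
#' of expected per-fragment proportions and the configuration as JSON.
#'
#' @param cfg A [simulation_config()].
#' @param fm Fragment map from [digest_genome()] (must cover the
#'   configured chromosomes and viewpoint).
#' @param dir Output directory for `reads.bam`, `truth.tsv`,
#'   `config.json`; `NULL` keeps everything in memory.
#' @return List with `reads` (alignment `GRanges` with `mapq`,
#'   `five_prime`), `truth` (data.frame fragment_id, expected_prop,
#'   spike_fold, is_cis), and if `dir` is given `bam`, `truth_path`,
#'   `config_path`.
#' @export
simulate_3cseq <- function(cfg, fm, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  vp_id <- locate_viewpoint_fragment(cfg$vp, fm)
  truth <- simulation_weights(cfg, fm)
  set.seed(cfg$seed + 1L)  # genome and reads draw from distinct streams
  frag_idx <- sample.int(length(fm), cfg$n_reads, replace = TRUE,
                         prob = truth$expected_prop)
  fs <- GenomicRanges::start(fm)[frag_idx]
  fe <- GenomicRanges::end(fm)[frag_idx]
  fw <- fe - fs + 1L
  minus <- stats::runif(cfg$n_reads) < 0.5
  informative <- stats::runif(cfg$n_reads) < cfg$informative_fraction
  fp <- integer(cfg$n_reads)
  fp[informative & !minus] <- fs[informative & !minus]
  fp[informative & minus] <- fe[informative & minus]
  ni <- !informative
  fp[ni] <- fs[ni] + floor(stats::runif(sum(ni)) * fw[ni])
  rl <- cfg$read_length
  start <- ifelse(minus, pmax(fs, fp - rl + 1L), fp)
  end <- ifelse(minus, fp, pmin(fe, fp + rl - 1L))
  reads <- GenomicRanges::GRanges(
    factor(as.character(GenomicRanges::seqnames(fm))[frag_idx],
           levels = GenomeInfoDb::seqlevels(fm)),
    IRanges::IRanges(start, end),
    strand = ifelse(minus, "-", "+"))
  GenomeInfoDb::seqlengths(reads) <- GenomeInfoDb::seqlengths(fm)
  reads$mapq <- 42L
  reads$five_prime <- as.integer(fp)
  out <- list(reads = reads, truth = truth, viewpoint_fragment = vp_id)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$bam <- write_reads_bam(reads, file.path(dir, "reads"))
    out$truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(truth, out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$config_path <- file.path(dir, "config.json")
    write_config_json(cfg, out$config_path)
  }
  out
}

#' Write simulated reads as a coordinate-sorted, indexed BAM
#'
#' Emits minimal single-end SAM records (sequence and quality omitted)
#' and converts them with `Rsamtools::asBam`, which sorts and indexes.
#'
#' @param reads Alignment `GRanges` with seqlengths set.
#' @param prefix Output path without extension; `<prefix>.bam` is created.
#' @return Path to the BAM file.
#' @export
write_reads_bam <- function(reads, prefix) {
  sl <- GenomeInfoDb::seqlengths(reads)
  if (anyNA(sl)) stop("reads need seqlengths to write a BAM header")
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl), con)
  n <- length(reads)
  if (n > 0L) {
    flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                   16L, 0L)
    cigar <- sprintf("%dM", GenomicRanges::width(reads))
    writeLines(sprintf("read%d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       seq_len(n), flag,
                       as.character(GenomicRanges::seqnames(reads)),
                       GenomicRanges::start(reads),
                       reads$mapq %||% 42L, cigar), con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_config_json <- function(cfg, path) {
  x <- unclass(cfg)
  if (methods::is(x$vp, "GRanges"))
    x$vp <- list(chrom = as.character(GenomicRanges::seqnames(x$vp)),
                 start = GenomicRanges::start(x$vp) - 1L,
                 end = GenomicRanges::end(x$vp),
                 name = x$vp$name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
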