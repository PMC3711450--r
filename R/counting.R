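#' Load aligned 3C-seq reads from a BAM or SAM file
#'
#' Reads single-end alignments, dropping unmapped, secondary and
#' supplementary records and records below `min_mapq`. Each retained read is
#' reduced to its aligned span, strand and strand-aware 5' position (the
#' ligation-junction end of a primer-trimmed 3C-seq read).
#'
#' @param path BAM or SAM file. SAM input is converted on the fly.
#' @param min_mapq Minimum mapping quality; default 10 removes most
#'   multi-mapping reads without discarding the bulk of the library.
#' @return A `GRanges` with metadata columns `mapq` and `five_prime`
#'   (1-based coordinate of the 5' base). The number of retained reads is
#'   reported as a message.
#' @export
load_alignments <- function(path, min_mapq = 10L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  stopifnot(min_mapq >= 0L)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("cannot read alignment file ", path, ": ",
                               conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    what = "mapq",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  ga <- tryCatch(GenomicAlignments::readGAlignments(bam, param = param),
                 error = function(e) stop("cannot read alignment file ",
                                          path, ": ", conditionMessage(e)))
  gr <- GenomicRanges::granges(ga, use.mcols = TRUE)
  mq <- gr$mapq
  mq[is.na(mq)] <- 0L  # MAPQ 255 ("unavailable") is kept; missing treated as 0
  gr <- gr[mq >= min_mapq]
  gr$five_prime <- five_prime_pos(gr)
  message(length(gr), " alignments retained from ", basename(path))
  gr
}

# strand-aware 5' coordinate (1-based): start on +, end on -
five_prime_pos <- function(reads) {
  ifelse(as.character(GenomicRanges::strand(reads)) == "-",
         GenomicRanges::end(reads), GenomicRanges::start(reads))
}

reads_five_prime <- function(reads) {
  fp <- reads$five_prime
  if (is.null(fp)) fp <- five_prime_pos(reads)
  fp
}

#' Collapse duplicate reads
#'
#' Keeps one read per identical (chromosome, 5' position, strand) tuple.
#' 3C-seq reads from the same ligation junction legitimately share a 5'
#' boundary, so deduplication is off by default in the counting functions.
#'
#' @param reads Alignment `GRanges` from [load_alignments()].
#' @return Deduplicated `GRanges`.
#' @export
collapse_duplicates <- function(reads) {
  key <- paste(GenomicRanges::seqnames(reads), reads_five_prime(reads),
               GenomicRanges::strand(reads))
  reads[!duplicated(key)]
}

#' Count reads per restriction fragment
#'
#' Assigns each read to the unique fragment containing its strand-aware 5'
#' position. With `informative_only`, a read is kept only when that 5'
#' position lies within `tolerance` bp of either fragment boundary — the
#' signature of a genuine ligation junction abutting a restriction site;
#' reads from incompletely digested or randomly sheared chromatin start
#' inside fragments and are discarded.
#'
#' @param reads Alignment `GRanges`.
#' @param fm Fragment map from [digest_genome()].
#' @param informative_only Keep only reads abutting restriction sites.
#' @param tolerance Maximal distance (bp) from a fragment boundary for a
#'   read to count as informative. Default 1 tolerates the single-base
#'   shifts that end-repair and alignment clipping commonly introduce; use
#'   0 for a strict boundary match.
#' @param collapse Collapse duplicate (chrom, 5', strand) reads first.
#' @return A region-signal `GRanges`: the fragment map with metadata columns
#'   `region_id`, `raw_count`, `rpm` (NA until [simple_rpm()]) and
#'   `norm_rpm` (NA until [powerlaw_normalize()]). Reads on chromosomes
#'   absent from the map are tallied in `attr(, "unassigned")`.
#' @export
count_per_fragment <- function(reads, fm, informative_only = FALSE,
                               tolerance = 1L, collapse = FALSE) {
  if (collapse) reads <- collapse_duplicates(reads)
  fp <- reads_five_prime(reads)
  chroms <- as.character(GenomicRanges::seqnames(reads))
  shared <- chroms %in% GenomeInfoDb::seqlevels(fm)
  unassigned <- sum(!shared)
  pts <- GenomicRanges::GRanges(
    factor(chroms[shared], levels = GenomeInfoDb::seqlevels(fm)),
    IRanges::IRanges(fp[shared], width = 1L))
  ov <- GenomicRanges::findOverlaps(pts, fm, ignore.strand = TRUE)
  hit_read <- S4Vectors::queryHits(ov)
  hit_frag <- S4Vectors::subjectHits(ov)
  unassigned <- unassigned + (length(pts) - length(unique(hit_read)))
  if (informative_only) {
    p <- GenomicRanges::start(pts)[hit_read]
    keep <- (p - GenomicRanges::start(fm)[hit_frag]) <= tolerance |
            (GenomicRanges::end(fm)[hit_frag] - p) <= tolerance
    hit_frag <- hit_frag[keep]
  }
  out <- fm
  out$region_id <- fm$fragment_id
  out$raw_count <- tabulate(hit_frag, nbins = length(fm))
  out$rpm <- NA_real_
  out$norm_rpm <- NA_real_
  attr(out, "unassigned") <- unassigned
  out
}

#' Count reads per genomic window
#'
#' Tiles each chromosome with fixed-size windows and assigns reads by their
#' strand-aware 5' position. In non-overlapping mode the windows partition
#' the chromosome (last window truncated); in overlapping mode windows
#' advance by half a window, so each read contributes to every window
#' containing its 5' position (at most two).
#'
#' @param reads Alignment `GRanges`.
#' @param chrom_sizes Named numeric vector of chromosome lengths, or a
#'   2-column data.frame (chrom, length), or a `Seqinfo`.
#' @param window Window size in bp, >= 1000.
#' @param overlapping Use half-window stepping.
#' @return A region-signal `GRanges` as in [count_per_fragment()], with
#'   `region_id` numbering the windows.
#' @export
count_per_window <- function(reads, chrom_sizes, window,
                             overlapping = FALSE) {
  sizes <- as_chrom_sizes(chrom_sizes)
  storage.mode(sizes) <- "integer"
  window <- as.integer(window)
  if (window < 1000L) stop("window must be at least 1000 bp")
  if (window > max(sizes))
    warning("window exceeds the longest chromosome; ",
            "one truncated window per chromosome")
  step <- if (overlapping) window %/% 2L else window
  win_list <- lapply(names(sizes), function(chrom) {
    starts <- seq.int(1L, sizes[[chrom]], by = step)
    ends <- pmin(starts + window - 1L, sizes[[chrom]])
    keep <- ends >= starts
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts[keep], ends[keep]))
  })
  wins <- do.call(c, win_list)
  GenomeInfoDb::seqlevels(wins) <- names(sizes)
  GenomeInfoDb::seqlengths(wins) <- sizes

  fp <- reads_five_prime(reads)
  chroms <- as.character(GenomicRanges::seqnames(reads))
  shared <- chroms %in% names(sizes)
  pts <- GenomicRanges::GRanges(
    factor(chroms[shared], levels = names(sizes)),
    IRanges::IRanges(fp[shared], width = 1L))
  wins$region_id <- seq_along(wins)
  wins$raw_count <- GenomicRanges::countOverlaps(wins, pts,
                                                 ignore.strand = TRUE)
  wins$rpm <- NA_real_
  wins$norm_rpm <- NA_real_
  attr(wins, "unassigned") <- sum(!shared)
  wins
}

as_chrom_sizes <- function(chrom_sizes) {
  if (methods::is(chrom_sizes, "Seqinfo"))
    return(GenomeInfoDb::seqlengths(chrom_sizes))
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.integer(chrom_sizes[[2L]])
    names(sizes) <- as.character(chrom_sizes[[1L]])
    return(sizes)
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes)))
    return(chrom_sizes)
  stop("chrom_sizes must be a named vector, 2-column data.frame or Seqinfo")
}

#' Read a 2-column chromosome-sizes TSV
#' @param path File with columns chrom, length (no header).
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          colClasses = c("character", "numeric"))
  sizes <- as.integer(df[[2L]]); names(sizes) <- df[[1L]]
  sizes
}

#' Write per-region counts as TSV
#'
#' Columns chrom, start (0-based), end, id, raw_count; used by the
#' command-line `count` step.
#' @param signals Region-signal `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(signals, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(signals)),
                   start = GenomicRanges::start(signals) - 1L,
                   end = GenomicRanges::end(signals),
                   id = signals$region_id,
                   raw_count = signals$raw_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
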