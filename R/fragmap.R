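#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each exact occurrence of the enzyme recognition
#' site and returns the resulting restriction fragments as a [GenomicRanges::GRanges]
#' tiling each chromosome without gaps or overlaps. Fragments are the native
#' resolution unit of viewpoint-anchored 3C-seq: each sequenced ligation
#' product maps to one fragment, so the fragment map underlies all
#' fragment-based counting and interaction calling.
#'
#' A cut is placed at the first base of the recognition site (the site
#' belongs to the downstream fragment); `cleavage_offset` shifts every cut
#' downstream by a fixed number of bases for enzymes where the staggered
#' cleavage position matters. The site may contain IUPAC ambiguity codes,
#' which are expanded to character classes; ambiguous letters in the
#' *genome* (e.g. `N` runs) never match. Palindromic sites — the usual case
#' for 6-cutters such as HindIII (`AAGCTT`) — are searched on the forward
#' strand only; a non-palindromic site triggers a warning and both strands
#' are searched.
#'
#' @param genome A named [Biostrings::DNAStringSet], a named character vector
#'   of sequences, or the path to a (optionally gzipped) FASTA file.
#' @param site Recognition site as an IUPAC string, length >= 4.
#' @param cleavage_offset Integer >= 0, bases between site start and the cut.
#' @return A `GRanges` with metadata column `fragment_id` (globally unique,
#'   ordered) and `metadata()` fields `enzyme_site` and `cleavage_offset`.
#'   Seqlengths are set to the chromosome lengths.
#' @examples
#' fm <- digest_genome(c(chrT = "GGGAAGCTTCCCCAAGCTTTT"), "AAGCTT")
#' width(fm)  # 3 10 8
#' @export
digest_genome <- function(genome, site, cleavage_offset = 0L) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("empty genome: no sequences to digest")
  site <- toupper(as.character(site))
  if (nchar(site) < 4L) stop("recognition site must be at least 4 bp")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site))
    stop("recognition site contains non-IUPAC characters: ", site)
  cleavage_offset <- as.integer(cleavage_offset)
  stopifnot(cleavage_offset >= 0L)

  pat <- Biostrings::DNAString(site)
  palindromic <- as.character(Biostrings::reverseComplement(pat)) == site
  if (!palindromic)
    warning("recognition site ", site,
            " is not palindromic; searching both strands")

  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  frag_list <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    subj <- genome[[i]]
    # IUPAC codes in the pattern expand; ambiguity codes in the subject
    # never match (fixed subject)
    hits <- Biostrings::start(Biostrings::matchPattern(
      pat, subj, fixed = c(pattern = FALSE, subject = TRUE)))
    if (!palindromic) {
      rc <- Biostrings::reverseComplement(pat)
      hits2 <- Biostrings::start(Biostrings::matchPattern(
        rc, subj, fixed = c(pattern = FALSE, subject = TRUE)))
      hits <- sort(unique(c(hits, hits2)))
    }
    cuts <- hits + cleavage_offset  # 1-based position of first base after cut
    cuts <- cuts[cuts >= 1L & cuts <= lens[i]]
    bounds <- sort(unique(c(1L, cuts, lens[i] + 1L)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    keep <- ends >= starts  # drop zero-length fragments
    frag_list[[i]] <- data.frame(chrom = chroms[i],
                                 start = starts[keep], end = ends[keep])
  }
  df <- do.call(rbind, frag_list)
  fm <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    seqinfo = GenomeInfoDb::Seqinfo(chroms, seqlengths = lens))
  fm$fragment_id <- seq_along(fm)
  S4Vectors::metadata(fm) <- list(enzyme_site = site,
                                  cleavage_offset = cleavage_offset)
  fm
}

# Coerce FASTA path / character vector / DNAStringSet to a named DNAStringSet
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    # keep only the first word of FASTA headers, like aligners do
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet, named character vector or FASTA path")
  if (length(genome) > 0L &&
      (is.null(names(genome)) || anyNA(names(genome)) ||
         any(names(genome) == "")))
    stop("all genome sequences must be named")
  genome
}

#' Define a viewpoint region
#'
#' The viewpoint is the fixed genomic fragment whose genome-wide contact
#' partners the assay captures. Coordinates are BED-style 0-based half-open,
#' matching the coordinates in which viewpoints are usually recorded.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval, `start < end`.
#' @param name Optional label.
#' @return A length-1 `GRanges` with a `name` metadata column.
#' @export
viewpoint <- function(chrom, start, end, name = "viewpoint") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("viewpoint requires start < end")
  vp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  vp$name <- name
  vp
}

#' Locate the restriction fragment containing a viewpoint
#'
#' Returns the `fragment_id` of the fragment with maximal overlap with the
#' viewpoint interval; ties are broken in favour of the fragment with the
#' lower start coordinate.
#'
#' @param vp A viewpoint `GRanges` (see [viewpoint()]).
#' @param fm A fragment map from [digest_genome()].
#' @return Integer fragment id.
#' @export
locate_viewpoint_fragment <- function(vp, fm) {
  stopifnot(length(vp) == 1L)
  if (!(as.character(GenomicRanges::seqnames(vp)) %in%
        GenomeInfoDb::seqlevels(fm)))
    stop("viewpoint chromosome ", as.character(GenomicRanges::seqnames(vp)),
         " absent from fragment map")
  ov <- GenomicRanges::findOverlaps(vp, fm, ignore.strand = TRUE)
  if (length(ov) == 0L) stop("viewpoint overlaps no fragment")
  cand <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    rep(GenomicRanges::ranges(vp), length(cand)),
    GenomicRanges::ranges(fm)[cand]))
  best <- cand[order(-w, GenomicRanges::start(fm)[cand])][1L]
  fm$fragment_id[best]
}

#' Write a fragment map as 4-column BED
#'
#' BED output is 0-based half-open; columns are chrom, start, end,
#' fragment_id.
#'
#' @param fm Fragment map `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(fm, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fm)),
                   start = GenomicRanges::start(fm) - 1L,
                   end = GenomicRanges::end(fm),
                   id = fm$fragment_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment map written by [write_fragment_bed()]
#'
#' @param path 4-column BED file (chrom, start, end, fragment_id), 0-based.
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A fragment map `GRanges`.
#' @export
read_fragment_bed <- function(path, seqlengths = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "id"),
                          colClasses = c("character", "numeric", "numeric",
                                         "integer"))
  fm <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  fm$fragment_id <- df$id
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(fm) <- seqlengths[GenomeInfoDb::seqlevels(fm)]
  fm
}
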