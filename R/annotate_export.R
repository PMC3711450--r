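#' Annotate significant interactions with nearby genes
#'
#' Reports every gene whose strand-aware proximity window — from
#' `upstream_bp` before the transcription start site to `downstream_bp`
#' past the transcription end site, mirrored for minus-strand genes —
#' overlaps at least one significant call. Each gene is reported once,
#' with its best (minimum-q) supporting call.
#'
#' @param calls An `interaction_calls` or `combined_calls` object, or any
#'   data.frame with chrom/start/end (0-based half-open), `q` and
#'   `significant` columns.
#' @param genes Gene models as a stranded `GRanges` with a `gene_name` (or
#'   `name`/`gene_id`) metadata column; see [read_gene_models()].
#' @param upstream_bp Window upstream of the gene start (default 50000).
#' @param downstream_bp Window downstream of the gene end (default 5000).
#' @return data.frame with gene, chrom, start, end (0-based), strand,
#'   best_q, best_call_id, n_calls; one row per reported gene, ordered by
#'   best_q.
#' @export
annotate_genes <- function(calls, genes, upstream_bp = 50000,
                           downstream_bp = 5000) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  if (!all(c("gene_name") %in% names(GenomicRanges::mcols(genes)))) {
    nm <- GenomicRanges::mcols(genes)
    genes$gene_name <- if (!is.null(nm$name)) nm$name else nm$gene_id
  }
  if (is.null(genes$gene_name)) stop("gene models need a name column")
  sig <- as.data.frame(calls)[calls$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), best_q = numeric(0),
                      best_call_id = integer(0), n_calls = integer(0)))
  call_gr <- GenomicRanges::GRanges(sig$chrom,
                                    IRanges::IRanges(sig$start + 1, sig$end))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  ext_start <- GenomicRanges::start(genes) -
    ifelse(minus, downstream_bp, upstream_bp)
  ext_end <- GenomicRanges::end(genes) +
    ifelse(minus, upstream_bp, downstream_bp)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(pmax(1, ext_start), ext_end))
  ov <- GenomicRanges::findOverlaps(win, call_gr, ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(annotate_genes(calls[integer(0), ], genes))
  gi <- S4Vectors::queryHits(ov)
  ci <- S4Vectors::subjectHits(ov)
  qv <- sig$q[ci]
  best <- tapply(seq_along(gi), gi, function(ii) ii[which.min(qv[ii])])
  gidx <- as.integer(names(best))
  bidx <- unlist(best)
  out <- data.frame(
    gene = as.character(genes$gene_name)[gidx],
    chrom = as.character(GenomicRanges::seqnames(genes))[gidx],
    start = GenomicRanges::start(genes)[gidx] - 1L,
    end = GenomicRanges::end(genes)[gidx],
    strand = as.character(GenomicRanges::strand(genes))[gidx],
    best_q = qv[bidx],
    best_call_id = sig$id[ci[bidx]],
    n_calls = as.integer(table(gi)[as.character(gidx)]))
  out <- out[order(out$best_q, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Read gene models from BED12/BED or GTF
#'
#' Thin wrapper over `rtracklayer::import`; GTF records are reduced to one
#' range per gene, named by the `gene_name` attribute (fallback
#' `gene_id`), BED records keep their `name` column.
#'
#' @param path BED or GTF file.
#' @return Stranded `GRanges` with a `gene_name` column.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading gene model files requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  mc <- GenomicRanges::mcols(gr)
  if (!is.null(mc$gene_name) || !is.null(mc$gene_id)) {  # GTF
    nm <- if (!is.null(mc$gene_name)) mc$gene_name else mc$gene_id
    nm[is.na(nm)] <- mc$gene_id[is.na(nm)]
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     name = as.character(nm))
    first <- df[!duplicated(df$name), ]
    first$start <- as.vector(tapply(df$start, df$name, min)[first$name])
    first$end <- as.vector(tapply(df$end, df$name, max)[first$name])
    out <- GenomicRanges::GRanges(first$chrom,
                                  IRanges::IRanges(first$start, first$end),
                                  strand = first$strand)
    out$gene_name <- first$name
    out
  } else {
    gr$gene_name <- mc$name
    gr
  }
}

#' Export region signals or calls to bedGraph
#'
#' UCSC bedGraph dialect: a `track type=bedGraph name=...` header followed
#' by `chrom<TAB>start<TAB>end<TAB>value` records in 0-based half-open
#' coordinates. Zero-valued regions are omitted. Overlapping regions are
#' rejected unless `allow_overlap` (for overlapping-window signals, which
#' genome browsers cannot stack in a single bedGraph track).
#'
#' @param x Region-signal `GRanges` or an `interaction_calls` /
#'   `combined_calls` data.frame.
#' @param path Output file.
#' @param value Column to export (default `"norm_rpm"` for signals,
#'   `"signal"` works for calls; `"q"` exports -log10 q).
#' @param name Track name.
#' @param allow_overlap Permit overlapping regions.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(x, path, value = "norm_rpm",
                            name = "viewcall", allow_overlap = FALSE) {
  if (methods::is(x, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1L,
                     end = GenomicRanges::end(x))
    df$value <- GenomicRanges::mcols(x)[[value]]
  } else {
    df <- as.data.frame(x)[, c("chrom", "start", "end")]
    v <- as.data.frame(x)[[value]]
    df$value <- if (value == "q") -log10(pmax(v, 1e-10)) else v
  }
  if (is.null(df$value)) stop("no column '", value, "' to export")
  if (!allow_overlap) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1, df$end))
    if (!IRanges::isDisjoint(gr))
      stop("overlapping regions cannot be exported to a single bedGraph ",
           "track; set allow_overlap = TRUE for overlapping-window signals")
  }
  df <- df[df$value != 0, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  if (nrow(df) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                       as.integer(df$end), format_num(df$value)), con)
  invisible(path)
}

# fixed-notation numbers at 6 significant digits, no trailing padding
format_num <- function(x) {
  out <- formatC(signif(x, 6), format = "fg", flag = "#", digits = 6)
  sub("\\.$", "", sub("(\\.[0-9]*?)0+$", "\\1", trimws(out)))
}

#' Export interaction calls to tab-delimited text
#'
#' Fixed column order (chrom, start, end, id, distance, raw_count, rpm,
#' signal, z, p, q, is_cis, significant — or the combined-calls columns),
#' floats at 6 significant digits, one row per region, 0-based half-open
#' coordinates.
#'
#' @param calls `interaction_calls`, `combined_calls` or plain data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_text <- function(calls, path) {
  df <- as.data.frame(calls)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Domainogram matrix around a viewpoint
#'
#' Repeats the window-based analysis for every window size from 2 kb to
#' 30 kb (1-kb steps, 29 rows by default): windows are tiled across
#' `[viewpoint - span_bp, viewpoint + span_bp]` on the cis chromosome,
#' counted, normalized and scored by the full calling pipeline, and the
#' q-value of the window covering each genomic position is recorded. The
#' result visualizes interactions at all scales at once, freeing the
#' analysis from a single arbitrary window size.
#'
#' @param reads Alignment `GRanges`.
#' @param vp Viewpoint `GRanges`.
#' @param chrom_sizes Chromosome sizes (named vector / data.frame /
#'   `Seqinfo`).
#' @param span_bp Half-width of the region around the viewpoint midpoint.
#' @param sizes Window sizes in bp (default `seq(2000, 30000, 1000)`).
#' @param config A [calling_config()].
#' @param grid_bp Column spacing of the position grid (default 1000).
#' @return Matrix of q-values, rows = window sizes, columns = genomic grid
#'   positions (1-based midpoint coordinates as column names); class
#'   `domainogram`, attributes `chrom`, `viewpoint`.
#' @export
domainogram_matrix <- function(reads, vp, chrom_sizes, span_bp,
                               sizes = seq(2000, 30000, by = 1000),
                               config = calling_config(),
                               grid_bp = 1000) {
  sizes <- as.integer(sizes)
  if (span_bp < max(sizes))
    stop("span_bp must be at least the largest window size")
  chrom <- as.character(GenomicRanges::seqnames(vp))[1L]
  all_sizes <- as_chrom_sizes(chrom_sizes)
  clen <- all_sizes[[chrom]]
  vmid <- (GenomicRanges::start(vp) + GenomicRanges::end(vp)) / 2
  lo <- max(1, floor(vmid - span_bp))
  hi <- min(clen, ceiling(vmid + span_bp))
  grid <- seq.int(lo + grid_bp / 2, hi, by = grid_bp)
  mat <- matrix(NA_real_, nrow = length(sizes), ncol = length(grid),
                dimnames = list(size = sizes, pos = round(grid)))
  chroms <- as.character(GenomicRanges::seqnames(reads))
  fp <- reads_five_prime(reads)
  cis <- chroms == chrom & fp >= lo & fp <= hi
  sub_reads <- reads[cis]
  for (r in seq_along(sizes)) {
    w <- sizes[r]
    starts <- seq.int(lo, hi - 1, by = w)
    wins <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, pmin(starts + w - 1, hi)))
    wins$region_id <- seq_along(wins)
    pts <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(reads_five_prime(sub_reads), width = 1L))
    wins$raw_count <- GenomicRanges::countOverlaps(wins, pts)
    wins$rpm <- NA_real_; wins$norm_rpm <- NA_real_
    sig <- simple_rpm(wins)
    sig <- tryCatch(powerlaw_normalize(sig, fit_powerlaw(sig, vp = vp)),
                    error = function(e) {
                      sig$norm_rpm <- sig$rpm
                      sig
                    })
    q <- rep(NA_real_, length(wins))
    cl <- tryCatch(call_interactions(sig, vp, config = config),
                   error = function(e) NULL)
    if (!is.null(cl)) q[cl$id] <- cl$q
    win_of <- findInterval(grid, starts)
    mat[r, ] <- q[win_of]
  }
  structure(mat, class = c("domainogram", "matrix"),
            chrom = chrom, viewpoint = vp)
}

#' Export a domainogram matrix as TSV
#'
#' Cells are written as `-log10(q)` capped at 10 (the color scale used for
#' domainogram heat maps); rows are window sizes, columns grid positions,
#' both kept as headers.
#'
#' @param mat A `domainogram` matrix from [domainogram_matrix()].
#' @param path Output file.
#' @param transform `"neglog10"` (default, capped at 10) or `"none"`.
#' @return `path`, invisibly.
#' @export
export_domainogram <- function(mat, path, transform = c("neglog10", "none")) {
  transform <- match.arg(transform)
  m <- unclass(mat)
  if (transform == "neglog10") m <- pmin(-log10(pmax(m, 1e-10)), 10)
  df <- data.frame(size = rownames(mat), m, check.names = FALSE)
  colnames(df) <- c("size", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heat-map rendering of a domainogram
#'
#' @param x A `domainogram` matrix.
#' @param ... Passed to [graphics::image()].
#' @method plot domainogram
#' @export
plot.domainogram <- function(x, ...) {
  m <- pmin(-log10(pmax(unclass(x), 1e-10)), 10)
  pos <- as.numeric(colnames(x)); size <- as.numeric(rownames(x))
  graphics::image(pos, size, t(m), xlab = paste0(attr(x, "chrom"), " (bp)"),
                  ylab = "window size (bp)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
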