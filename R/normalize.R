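#' Simple reads-per-million normalization
#'
#' Scales raw counts to a 1-million-read library:
#' `rpm_i = raw_count_i / sum(raw_count) * 1e6`.
#'
#' @param signals Region-signal `GRanges` from the counting functions.
#' @return The same `GRanges` with the `rpm` column filled.
#' @export
simple_rpm <- function(signals) {
  total <- sum(signals$raw_count)
  if (total <= 0) stop("all region counts are zero; cannot compute RPM")
  signals$rpm <- signals$raw_count / total * 1e6
  signals
}

# Riemann zeta via partial sum + integral tail; s > 1
zeta_fn <- function(s, n = 1e6) {
  sum(seq_len(n)^(-s)) + n^(1 - s) / (s - 1)
}

#' Reference offset of the power-law normalization
#'
#' The reference reverse-cumulative law is `R_ref(t) = 10^l_ref * t^alpha_ref`
#' with `l_ref` fixed so that a library drawn from the reference law totals
#' `n0` reads: since the expected read total of a discrete law with
#' `P(count >= t) = C * t^alpha` is `C * zeta(-alpha)`,
#' `l_ref = log10(n0 / zeta(-alpha_ref))`. Only relative signals matter
#' downstream, so the choice of constant is a convention; this one makes a
#' million-read reference library map onto itself.
#'
#' @param alpha_ref Reference exponent (default -1.35).
#' @param n0 Reference library size in reads (default 1e6).
#' @return log10 reference offset (scalar).
#' @export
powerlaw_reference_offset <- function(alpha_ref = -1.35, n0 = 1e6) {
  log10(n0 / zeta_fn(-alpha_ref))
}

#' Sample counts from the reference power law
#'
#' Inverse-transform sampling of the discrete distribution whose reverse
#' cumulative is exactly `P(count >= t) = (t / tmin)^alpha` for integer
#' `t >= tmin`. With `tmin = 1` this is the full reference law; with
#' `tmin` equal to the fit threshold it is the reference law over the
#' fitting domain.
#'
#' @param n Number of counts to draw.
#' @param alpha Exponent of the reverse-cumulative law (default -1.35).
#' @param tmin Support lower bound (default 1).
#' @return Integer-valued numeric vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha = -1.35, tmin = 1) {
  stopifnot(alpha < 0, tmin >= 1)
  floor(tmin * stats::runif(n)^(1 / alpha))
}

#' Fit the reverse-cumulative power law to region counts
#'
#' Regions with fewer than `min_count` reads are removed, as is the
#' viewpoint fragment and its two neighbours (self-ligation signal) when a
#' viewpoint is supplied. The reverse-cumulative frequency `R(t)` — the
#' number of surviving regions with count >= t — is evaluated at every
#' distinct observed count and regressed by unweighted ordinary least
#' squares in log10-log10 space, giving the library's offset and slope.
#'
#' @param x Region-signal `GRanges`, or a bare numeric vector of counts.
#' @param vp Optional viewpoint `GRanges`; its fragment and the two
#'   adjacent regions are excluded from the fit.
#' @param min_count Minimum count for a region to enter the fit
#'   (default 50).
#' @param alpha_ref,n0 Reference-law constants (see
#'   [powerlaw_reference_offset()]).
#' @return An object of class `powerlaw_fit`: list with `slope`, `offset`,
#'   `alpha_ref`, `n0`, `l_ref`, `min_count`, `n_regions_fit`.
#' @export
fit_powerlaw <- function(x, vp = NULL, min_count = 50,
                         alpha_ref = -1.35, n0 = 1e6) {
  if (methods::is(x, "GRanges")) {
    counts <- x$raw_count
    if (!is.null(vp)) {
      ov <- GenomicRanges::findOverlaps(vp, x, ignore.strand = TRUE)
      if (length(ov) > 0L) {
        i <- S4Vectors::subjectHits(ov)
        drop <- unique(c(i - 1L, i, i + 1L))
        drop <- drop[drop >= 1L & drop <= length(counts)]
        # adjacency is within-chromosome only
        drop <- drop[as.character(GenomicRanges::seqnames(x))[drop] ==
                       as.character(GenomicRanges::seqnames(vp))[1L]]
        counts <- counts[-drop]
      }
    }
  } else counts <- as.numeric(x)
  counts <- counts[counts >= min_count]
  tt <- sort(unique(counts))
  if (length(tt) < 3L)
    stop("fewer than 3 distinct count values survive the min_count filter; ",
         "lower min_count (currently ", min_count, ")")
  # reverse cumulative at each distinct observed count
  n_ge <- rev(cumsum(rev(tabulate(factor(counts, levels = tt)))))
  fit <- stats::lm.fit(cbind(1, log10(tt)), log10(n_ge))
  structure(list(slope = unname(fit$coefficients[2L]),
                 offset = unname(fit$coefficients[1L]),
                 alpha_ref = alpha_ref, n0 = n0,
                 l_ref = powerlaw_reference_offset(alpha_ref, n0),
                 min_count = min_count,
                 n_regions_fit = length(counts)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law reverse-cumulative fit\n")
  cat(sprintf("  slope  %8.4f   (reference alpha %.2f)\n",
              x$slope, x$alpha_ref))
  cat(sprintf("  offset %8.4f   (reference l_ref %.4f, n0 %g)\n",
              x$offset, x$l_ref, x$n0))
  cat(sprintf("  fitted on %d regions with count >= %g\n",
              x$n_regions_fit, x$min_count))
  invisible(x)
}

#' @method coef powerlaw_fit
#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(offset = object$offset, slope = object$slope)
}

#' Power-law normalization of region counts
#'
#' Maps each raw count `t > 0` onto the reference power law through the
#' fitted line:
#' `t' = 10^((offset + slope * log10(t) - l_ref) / alpha_ref)`.
#' The mapping is strictly increasing, so ranks and ties are preserved;
#' zero counts map to zero. A library whose fitted line coincides with the
#' reference line is left unchanged.
#'
#' @param signals Region-signal `GRanges`.
#' @param fit A `powerlaw_fit` from [fit_powerlaw()].
#' @return `signals` with the `norm_rpm` column filled (normalized
#'   reads-per-million on the scale of the `n0`-read reference library).
#' @export
powerlaw_normalize <- function(signals, fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  t <- signals$raw_count
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- 10^((fit$offset + fit$slope * log10(t[pos]) - fit$l_ref) /
                    fit$alpha_ref)
  signals$norm_rpm <- out
  signals
}

#' Write normalized signals as TSV (+ fit parameters as JSON sidecar)
#'
#' @param signals Region-signal `GRanges` with rpm/norm_rpm filled.
#' @param path Output TSV; the fit is written to `<path>.json`.
#' @param fit Optional `powerlaw_fit` to record.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path, fit = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(signals)),
                   start = GenomicRanges::start(signals) - 1L,
                   end = GenomicRanges::end(signals),
                   id = signals$region_id,
                   raw_count = signals$raw_count,
                   rpm = signif(signals$rpm, 6),
                   norm_rpm = signif(signals$norm_rpm, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit))
    jsonlite::write_json(unclass(fit), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
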