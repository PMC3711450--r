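#' Fisher's combined probability test
#'
#' Combines k independent p-values for the same region into one:
#' `X = -2 * sum(log(p_i))` follows a chi-square distribution with 2k
#' degrees of freedom under the joint null, and the combined p-value is its
#' upper tail at X.
#'
#' @param p Non-empty vector of p-values in (0, 1\]. Exact zeros are clamped
#'   to the smallest positive double with a warning.
#' @return Combined p-value (scalar).
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("fisher_combine needs at least one p-value")
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Combine interaction calls across biological replicates
#'
#' Each replicate is first analysed on its own ([call_interactions()] on an
#' identical fragment map or window grid). Candidate regions are then the
#' union (significant in at least one replicate) or the intersection
#' (significant in all replicates) of the per-replicate significant sets —
#' intersection removes signals originating from random ligation events,
#' which rarely recur across independently prepared libraries. Raw counts,
#' RPM and normalized RPM are averaged arithmetically over *all* replicates
#' (including those where a region fell short of significance, so the
#' averages are representative, with the `support` column exposing the
#' asymmetry). Per-replicate p-values are combined with
#' [fisher_combine()], and q-values are recomputed on the combined batch.
#'
#' @param call_sets List of k `interaction_calls` objects sharing the same
#'   region grid (identical `id` sets).
#' @param method `"union"` or `"intersection"`.
#' @param fdr_level Cutoff on the recomputed combined q-values.
#' @return An object of class `combined_calls`: data.frame with the region
#'   columns, `mean_raw_count`, `mean_rpm`, `mean_signal`, per-replicate
#'   `p.1 ... p.k`, `p_combined`, `q`, `support`, `is_cis`, `significant`,
#'   sorted by q.
#' @export
combine_replicates <- function(call_sets, method = c("union", "intersection"),
                               fdr_level = 0.05) {
  method <- match.arg(method)
  stopifnot(is.list(call_sets), length(call_sets) >= 1L)
  k <- length(call_sets)
  ids <- lapply(call_sets, function(s) sort(s$id))
  for (i in seq_len(k)[-1L]) {
    if (!identical(ids[[1L]], ids[[i]])) {
      bad <- c(setdiff(ids[[i]], ids[[1L]]), setdiff(ids[[1L]], ids[[i]]))
      stop("replicate ", i, " is on a different region grid than replicate ",
           "1 (first mismatching region id: ", bad[1L], ")")
    }
  }
  ord <- lapply(call_sets, function(s) s[order(s$id), ])
  sig_sets <- lapply(ord, function(s) s$id[s$significant])
  cand <- if (method == "union") Reduce(union, sig_sets)
          else Reduce(intersect, sig_sets)
  base <- ord[[1L]]
  sel <- base$id %in% cand
  if (sum(sel) == 0L) {
    out <- base[integer(0), c("chrom", "start", "end", "id", "distance",
                              "is_cis")]
    out$mean_raw_count <- numeric(0); out$mean_rpm <- numeric(0)
    out$mean_signal <- numeric(0)
    out$p_combined <- numeric(0); out$q <- numeric(0)
    out$support <- integer(0); out$significant <- logical(0)
    return(structure(out, class = c("combined_calls", "data.frame"),
                     method = method, k = k, fdr_level = fdr_level))
  }
  pmat <- sapply(ord, function(s) s$p[sel])
  pmat <- matrix(pmat, ncol = k)
  out <- base[sel, c("chrom", "start", "end", "id", "distance", "is_cis")]
  out$mean_raw_count <- rowMeans(matrix(
    sapply(ord, function(s) s$raw_count[sel]), ncol = k))
  out$mean_rpm <- rowMeans(matrix(
    sapply(ord, function(s) s$rpm[sel]), ncol = k))
  out$mean_signal <- rowMeans(matrix(
    sapply(ord, function(s) s$signal[sel]), ncol = k))
  for (i in seq_len(k)) out[[paste0("p.", i)]] <- pmat[, i]
  out$p_combined <- apply(pmat, 1L, fisher_combine)
  qv <- if (nrow(out) >= 10L) qvalues(out$p_combined, fdr_level = fdr_level)
        else qvalues(out$p_combined, fdr_level = fdr_level,
                     pi0_method = "fixed")
  out$q <- qv$qvalue
  out$support <- rowSums(matrix(
    sapply(ord, function(s) s$significant[sel]), ncol = k))
  out$significant <- qv$significant
  out <- out[order(out$q, out$p_combined), ]
  rownames(out) <- NULL
  structure(out, class = c("combined_calls", "data.frame"),
            method = method, k = k, fdr_level = fdr_level, pi0 = qv$pi0)
}

#' @export
print.combined_calls <- function(x, n = 10L, ...) {
  cat(sprintf("Combined calls (%s of %d replicates): %d candidate regions, ",
              attr(x, "method"), attr(x, "k"), nrow(x)),
      sprintf("%d significant at q <= %g\n", sum(x$significant),
              attr(x, "fdr_level")))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}
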