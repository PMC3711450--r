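#' Calling configuration
#'
#' Bundles the tunable parameters of interaction calling: the FDR level at
#' which a q-value is declared significant, the smoothing parameter of the
#' cis distance-decay spline, and the width of the region around the
#' viewpoint excluded from the trans background statistics.
#'
#' @param fdr_level Significance cutoff on q-values, in (0,1). Default 0.05.
#' @param spar Smoothing parameter of the cubic smoothing spline, normally
#'   in \[0.06, 0.4\]; default 0.1.
#' @param trans_exclusion_bp Half-width (bp) of the viewpoint-centred zone
#'   excluded from the global mean/SD used for trans scoring. Default 1e5.
#' @param signed_distance Fit the cis background against signed rather than
#'   absolute distance.
#' @param allow_spar_outside Permit `spar` outside \[0.06, 0.4\].
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(fdr_level = 0.05, spar = 0.1,
                           trans_exclusion_bp = 1e5,
                           signed_distance = FALSE,
                           allow_spar_outside = FALSE) {
  stopifnot(fdr_level > 0, fdr_level < 1, trans_exclusion_bp >= 0)
  structure(list(fdr_level = fdr_level, spar = spar,
                 trans_exclusion_bp = trans_exclusion_bp,
                 signed_distance = signed_distance,
                 allow_spar_outside = allow_spar_outside),
            class = "calling_config")
}

# signed distance (bp) from region midpoints to the viewpoint midpoint
region_distance <- function(signals, vp) {
  mid <- (GenomicRanges::start(signals) + GenomicRanges::end(signals)) / 2
  vmid <- (GenomicRanges::start(vp) + GenomicRanges::end(vp)) / 2
  d <- mid - vmid
  d[as.character(GenomicRanges::seqnames(signals)) !=
      as.character(GenomicRanges::seqnames(vp))[1L]] <- NA_real_
  d
}

# indices of the viewpoint region and its within-chromosome neighbours
viewpoint_region_idx <- function(signals, vp, flank = 1L) {
  ov <- GenomicRanges::findOverlaps(vp, signals, ignore.strand = TRUE)
  i <- S4Vectors::subjectHits(ov)
  if (length(i) == 0L) return(integer(0))
  idx <- unique(unlist(lapply(i, function(k) (k - flank):(k + flank))))
  idx <- idx[idx >= 1L & idx <= length(signals)]
  idx[as.character(GenomicRanges::seqnames(signals))[idx] ==
        as.character(GenomicRanges::seqnames(vp))[1L]]
}

signal_values <- function(signals, value = "norm_rpm") {
  v <- GenomicRanges::mcols(signals)[[value]]
  if (is.null(v) || all(is.na(v)))
    stop("signal column '", value, "' is empty; run the normalization first")
  v
}

#' Fit the cis distance-decay background
#'
#' Contact frequency falls off systematically with genomic distance from
#' the viewpoint; this proximity signal is background, not interaction.
#' The background is estimated by a cubic smoothing spline
#' ([stats::smooth.spline]) of the normalized signal against distance to
#' the viewpoint midpoint (absolute distance by default, pooling the up-
#' and downstream arms). The viewpoint region and its immediate neighbours
#' are excluded (self-ligation), as are zero-signal regions, which would
#' otherwise drag the spline toward zero in the sparse far-cis tail; the
#' expected value for every region — including the zeros — is read off the
#' fitted curve and clamped at 0. A single residual standard deviation
#' (n-1 denominator) is computed over the fitted regions.
#'
#' @param signals Region-signal `GRanges` restricted to (or containing) the
#'   viewpoint chromosome, with `norm_rpm` (or `value`) filled.
#' @param vp Viewpoint `GRanges`.
#' @param spar Smoothing parameter; the spline's roughness penalty is
#'   `lambda = r * 256^(3*spar - 1)` with `r` the usual design-dependent
#'   scale factor. Values in \[0.06, 0.4\] give a useful range of stiffness;
#'   0.1 is the default.
#' @param signed_distance Fit against signed instead of absolute distance.
#' @param value Signal column to model (default `"norm_rpm"`).
#' @param allow_spar_outside Permit `spar` outside \[0.06, 0.4\].
#' @return An object of class `cis_background`: list with `expected` (one
#'   value per cis region of `signals`), `residual_sd`, `spar`, `fit_idx`
#'   (regions the spline was fitted on), `cis_idx`, `distance`.
#' @export
fit_cis_background <- function(signals, vp, spar = 0.1,
                               signed_distance = FALSE,
                               value = "norm_rpm",
                               allow_spar_outside = FALSE) {
  if ((spar < 0.06 || spar > 0.4) && !allow_spar_outside)
    stop("spar must lie in [0.06, 0.4] (got ", spar,
         "); set allow_spar_outside = TRUE to override")
  obs_all <- signal_values(signals, value)
  d <- region_distance(signals, vp)
  cis_idx <- which(!is.na(d))
  if (length(cis_idx) == 0L) stop("no regions on the viewpoint chromosome")
  vp_idx <- viewpoint_region_idx(signals, vp)
  fit_idx <- setdiff(cis_idx[obs_all[cis_idx] > 0], vp_idx)
  if (length(fit_idx) < 30L)
    stop("need at least 30 non-zero cis regions outside the viewpoint to ",
         "fit the background (got ", length(fit_idx), ")")
  if (stats::sd(obs_all[fit_idx]) == 0)
    stop("degenerate cis background: residual standard deviation is 0 ",
         "(constant signal)")
  x <- if (signed_distance) d else abs(d)
  sp <- stats::smooth.spline(x[fit_idx], obs_all[fit_idx], spar = spar)
  expected <- pmax(0, stats::predict(sp, x[cis_idx])$y)
  fitted_exp <- pmax(0, stats::predict(sp, x[fit_idx])$y)
  res <- obs_all[fit_idx] - fitted_exp
  residual_sd <- stats::sd(res)
  if (!is.finite(residual_sd) || residual_sd <= 0)
    stop("degenerate cis background: residual standard deviation is 0")
  structure(list(expected = expected, residual_sd = residual_sd,
                 spar = spar, signed_distance = signed_distance,
                 fit_idx = fit_idx, cis_idx = cis_idx,
                 distance = d[cis_idx], value = value, spline = sp),
            class = "cis_background")
}

#' @export
print.cis_background <- function(x, ...) {
  cat("Cis distance-decay background (cubic smoothing spline)\n")
  cat(sprintf("  spar %.3f, %s distance, fitted on %d regions\n",
              x$spar, if (x$signed_distance) "signed" else "absolute",
              length(x$fit_idx)))
  cat(sprintf("  residual SD %.4g (%s units)\n", x$residual_sd, x$value))
  invisible(x)
}

#' Z-scores of cis regions against the distance-decay background
#'
#' `z = (obs - exp) / SD` with `exp` the spline background and `SD` the
#' single residual standard deviation of the fit.
#'
#' @param signals The same region-signal `GRanges` the background was
#'   fitted on.
#' @param bg A `cis_background`.
#' @return Numeric vector of z-scores, one per cis region (in `bg$cis_idx`
#'   order).
#' @export
zscores_cis <- function(signals, bg) {
  stopifnot(inherits(bg, "cis_background"))
  if (bg$residual_sd <= 0) stop("degenerate background: residual SD is 0")
  obs <- signal_values(signals, bg$value)[bg$cis_idx]
  (obs - bg$expected) / bg$residual_sd
}

#' Z-scores of trans regions against the global signal distribution
#'
#' Trans chromosomes carry no proximity bias, so no distance scaling is
#' needed: the mean and standard deviation (n-1) of the signal over the
#' whole data set — excluding regions within `exclusion_bp` of the
#' viewpoint, whose signal is proximity-driven — serve as the null, and
#' every trans-chromosome region is scored as `z = (obs - mean) / SD`.
#'
#' @param signals Genome-wide region-signal `GRanges`.
#' @param vp Viewpoint `GRanges`.
#' @param exclusion_bp Half-width of the excluded viewpoint zone
#'   (default 1e5).
#' @param value Signal column (default `"norm_rpm"`).
#' @param min_regions Minimum regions required outside the exclusion zone
#'   (default 30).
#' @return Numeric vector of z-scores for the trans regions, with
#'   `attr(, "trans_idx")` giving their indices in `signals` and
#'   `attr(, "mean")`/`attr(, "sd")` the global statistics.
#' @export
zscores_trans <- function(signals, vp, exclusion_bp = 1e5,
                          value = "norm_rpm", min_regions = 30L) {
  obs_all <- signal_values(signals, value)
  d <- region_distance(signals, vp)
  keep <- is.na(d) | abs(d) > exclusion_bp
  if (sum(keep) < min_regions)
    stop("need at least ", min_regions,
         " regions outside the viewpoint exclusion zone")
  mu <- mean(obs_all[keep])
  sdev <- stats::sd(obs_all[keep])
  if (!is.finite(sdev) || sdev <= 0)
    stop("degenerate trans background: global SD is 0")
  trans_idx <- which(is.na(d))
  z <- (obs_all[trans_idx] - mu) / sdev
  attr(z, "trans_idx") <- trans_idx
  attr(z, "mean") <- mu
  attr(z, "sd") <- sdev
  z
}

#' Upper-tail normal p-values from z-scores
#'
#' Only enrichment over the background constitutes an interaction, so
#' p-values are one-sided: `p = 1 - Phi(z)`.
#'
#' @param z Numeric z-scores.
#' @return p-values in \[0, 1\].
#' @export
pvalues_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' q-values with bootstrap pi0 estimation
#'
#' Storey-style q-values: the proportion of true nulls `pi0` is estimated
#' on the grid lambda = 0.05, 0.10, ..., 0.95 as
#' `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`, and the bootstrap
#' (100 resamples) picks the lambda whose `pi0` estimate minimizes the
#' estimated mean squared error around the most conservative plug-in
#' (the minimum over the grid). q-values are the pi0-scaled step-up:
#' `q_(i) = min_(j>=i) pi0 * m * p_(j) / j`; with `pi0 = 1` this is exactly
#' Benjamini-Hochberg.
#'
#' @param p p-values in \[0, 1\], length >= 10 for the bootstrap.
#' @param fdr_level Cutoff for the `significant` flags (default 0.05).
#' @param pi0_method `"bootstrap"` (default) or `"fixed"` (pi0 = 1,
#'   i.e. plain Benjamini-Hochberg).
#' @param n_boot Bootstrap resamples (default 100).
#' @return List with `qvalue`, `pi0`, `significant` (q <= fdr_level).
#' @export
qvalues <- function(p, fdr_level = 0.05,
                    pi0_method = c("bootstrap", "fixed"), n_boot = 100L) {
  pi0_method <- match.arg(pi0_method)
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (pi0_method == "bootstrap") {
    if (m < 10L) stop("bootstrap pi0 estimation needs at least 10 p-values")
    pi0 <- pi0_bootstrap(p, n_boot = n_boot)
  } else pi0 <- 1
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalue = q, pi0 = pi0, significant = q <= fdr_level)
}

# Storey bootstrap pi0: lambda minimizing estimated MSE of pi0(lambda)
# around the grid minimum
pi0_bootstrap <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          n_boot = 100L) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
  # lambda beyond the support of p (no exceedances) carries no information
  # about pi0 and would otherwise drag the estimate to an exact 0
  keep <- pi0_l > 0
  if (!any(keep)) return(1)
  lambda <- lambda[keep]
  pi0_l <- pi0_l[keep]
  # a super-uniform p distribution (conservative null: the bulk of the
  # grid estimates pi0 >= 1) admits no pi0 < 1; the tail estimates are
  # then edge artefacts of the bounded p support, not signal
  if (stats::median(pi0_l) >= 1) return(1)
  pi0_min <- min(pi0_l)
  mse <- numeric(length(lambda))
  for (b in seq_len(n_boot)) {
    pb <- p[sample.int(m, m, replace = TRUE)]
    pi0_b <- vapply(lambda, function(l) sum(pb > l) / (m * (1 - l)), 0)
    mse <- mse + (pi0_b - pi0_min)^2
  }
  pi0 <- pi0_l[which.min(mse)]
  min(max(pi0, .Machine$double.eps), 1)
}

#' Call cis and trans interactions for a viewpoint
#'
#' Scores every region against its null: cis regions against the
#' smoothing-spline distance-decay background
#' ([fit_cis_background()] / [zscores_cis()]), trans regions against the
#' global signal distribution ([zscores_trans()]). Upper-tail normal
#' p-values are converted to q-values separately within the cis and the
#' trans batch — the two batches answer different null hypotheses, and
#' pooling them would let the dense cis batch dictate pi0 for trans.
#'
#' @param signals Genome-wide region-signal `GRanges` with `norm_rpm`
#'   filled (use `value` to score another column).
#' @param vp Viewpoint `GRanges`.
#' @param config A [calling_config()].
#' @param value Signal column to score (default `"norm_rpm"`).
#' @return An object of class `interaction_calls`: a data.frame with
#'   columns chrom, start (0-based), end, id, distance, raw_count, rpm,
#'   signal, z, p, q, is_cis, significant, sorted by q then decreasing
#'   |z|. Attributes: `config`, `viewpoint`, `pi0_cis`, `pi0_trans`,
#'   `background`.
#' @export
call_interactions <- function(signals, vp, config = calling_config(),
                              value = "norm_rpm") {
  stopifnot(inherits(config, "calling_config"))
  obs <- signal_values(signals, value)
  bg <- fit_cis_background(signals, vp, spar = config$spar,
                           signed_distance = config$signed_distance,
                           value = value,
                           allow_spar_outside = config$allow_spar_outside)
  z_cis <- zscores_cis(signals, bg)
  p_cis <- pvalues_from_z(z_cis)
  q_cis <- qvalues(p_cis, fdr_level = config$fdr_level)

  d <- region_distance(signals, vp)
  trans_idx <- which(is.na(d))
  if (length(trans_idx) > 0L) {
    z_trans <- zscores_trans(signals, vp,
                             exclusion_bp = config$trans_exclusion_bp,
                             value = value)
    p_trans <- pvalues_from_z(as.numeric(z_trans))
    q_trans <- qvalues(p_trans, fdr_level = config$fdr_level)
    pi0_trans <- q_trans$pi0
  } else {
    z_trans <- numeric(0); p_trans <- numeric(0)
    q_trans <- list(qvalue = numeric(0), significant = logical(0))
    pi0_trans <- NA_real_
  }

  idx <- c(bg$cis_idx, trans_idx)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(signals))[idx],
    start = GenomicRanges::start(signals)[idx] - 1L,
    end = GenomicRanges::end(signals)[idx],
    id = GenomicRanges::mcols(signals)$region_id[idx],
    distance = c(bg$distance, rep(NA_real_, length(trans_idx))),
    raw_count = GenomicRanges::mcols(signals)$raw_count[idx],
    rpm = GenomicRanges::mcols(signals)$rpm[idx],
    signal = obs[idx],
    z = c(z_cis, as.numeric(z_trans)),
    p = c(p_cis, p_trans),
    q = c(q_cis$qvalue, q_trans$qvalue),
    is_cis = rep(c(TRUE, FALSE), c(length(bg$cis_idx), length(trans_idx))),
    significant = c(q_cis$significant, q_trans$significant))
  df <- df[order(df$q, -abs(df$z)), ]
  rownames(df) <- NULL
  structure(df, class = c("interaction_calls", "data.frame"),
            config = config, viewpoint = vp,
            pi0_cis = q_cis$pi0, pi0_trans = pi0_trans, background = bg)
}

#' @export
print.interaction_calls <- function(x, n = 10L, ...) {
  cfg <- attr(x, "config")
  vp <- attr(x, "viewpoint")
  cat(sprintf("Interaction calls for viewpoint %s:%d-%d (%s)\n",
              as.character(GenomicRanges::seqnames(vp)),
              GenomicRanges::start(vp) - 1L, GenomicRanges::end(vp),
              vp$name))
  cat(sprintf("  %d regions scored (%d cis, %d trans); ",
              nrow(x), sum(x$is_cis), sum(!x$is_cis)))
  cat(sprintf("%d significant at q <= %g\n",
              sum(x$significant), cfg$fdr_level))
  cat(sprintf("  pi0: cis %.3f, trans %s\n", attr(x, "pi0_cis"),
              if (is.na(attr(x, "pi0_trans"))) "-" else
                sprintf("%.3f", attr(x, "pi0_trans"))))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @method summary interaction_calls
#' @export
summary.interaction_calls <- function(object, ...) {
  cfg <- attr(object, "config")
  sig <- object[object$significant, ]
  out <- list(n_regions = nrow(object),
              n_cis = sum(object$is_cis),
              n_trans = sum(!object$is_cis),
              n_significant = nrow(sig),
              n_significant_cis = sum(sig$is_cis),
              n_significant_trans = sum(!sig$is_cis),
              fdr_level = cfg$fdr_level,
              pi0_cis = attr(object, "pi0_cis"),
              pi0_trans = attr(object, "pi0_trans"))
  class(out) <- "summary.interaction_calls"
  out
}

#' @export
print.summary.interaction_calls <- function(x, ...) {
  cat(sprintf("%d regions (%d cis / %d trans); %d significant at q <= %g",
              x$n_regions, x$n_cis, x$n_trans, x$n_significant,
              x$fdr_level),
      sprintf("(%d cis, %d trans)\n", x$n_significant_cis,
              x$n_significant_trans))
  invisible(x)
}

#' Plot cis interaction signals against distance to the viewpoint
#'
#' Base-graphics rendering of the exported call table: signal versus
#' distance, background spline expectation as a line, significant calls
#' highlighted.
#'
#' @param x An `interaction_calls` object.
#' @param max_distance Restrict the x-axis to \|distance\| below this (bp).
#' @param ... Passed to [graphics::plot()].
#' @method plot interaction_calls
#' @export
plot.interaction_calls <- function(x, max_distance = Inf, ...) {
  cis <- x[x$is_cis & abs(x$distance) <= max_distance, ]
  bg <- attr(x, "background")
  graphics::plot(cis$distance, cis$signal, pch = 16, cex = 0.4,
                 col = "grey50", xlab = "distance to viewpoint (bp)",
                 ylab = "normalized signal (RPM)", ...)
  o <- order(bg$distance)
  keep <- abs(bg$distance[o]) <= max_distance
  graphics::lines(bg$distance[o][keep], bg$expected[o][keep],
                  col = "blue", lwd = 1.5)
  sig <- cis[cis$significant, ]
  graphics::points(sig$distance, sig$signal, pch = 16, cex = 0.6,
                   col = "red")
  invisible(x)
}
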