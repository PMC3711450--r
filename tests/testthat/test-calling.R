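# regular 1-kb region grid on one chromosome with given signal values
grid_signals <- function(values, chrom = "cisC", width = 1000L) {
  n <- length(values)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(seq(1L, by = width,
                                                    length.out = n),
                                                width = width))
  gr$region_id <- seq_len(n)
  gr$raw_count <- round(values)
  gr$rpm <- values
  gr$norm_rpm <- values
  gr
}

test_that("a noiseless decay curve is reproduced by the spline", {
  n <- 201
  mid_region <- (n + 1) / 2
  vp <- viewpoint("cisC", (mid_region - 1) * 1000, mid_region * 1000)
  d_kb <- abs(seq_len(n) - mid_region)
  sig <- grid_signals(1000 / (1 + d_kb))
  bg <- fit_cis_background(sig, vp, spar = 0.1)
  fit_vals <- GenomicRanges::mcols(sig)$norm_rpm[bg$fit_idx]
  exp_vals <- bg$expected[match(bg$fit_idx, bg$cis_idx)]
  # the spline reproduces the noiseless curve: tiny residual scale and
  # near-perfect agreement between expectation and signal
  expect_lt(bg$residual_sd / 1000, 0.05)
  expect_lt(max(abs(exp_vals - fit_vals)) / 1000, 0.05)
  expect_equal(cor(exp_vals, fit_vals), 1, tolerance = 1e-3)
})

test_that("constant signal gives a degenerate background error", {
  vp <- viewpoint("cisC", 50000, 51000)
  sig <- grid_signals(rep(10, 101))
  expect_error(fit_cis_background(sig, vp), "residual standard deviation")
})

test_that("spar outside the documented range needs an explicit override", {
  vp <- viewpoint("cisC", 50000, 51000)
  sig <- grid_signals(1000 / (1 + abs(seq_len(101) - 51)))
  expect_error(fit_cis_background(sig, vp, spar = 0.5), "0.06")
  expect_silent(fit_cis_background(sig, vp, spar = 0.5,
                                   allow_spar_outside = TRUE))
})

test_that("cis z-scores are centred residuals in SD units", {
  set.seed(41)
  n <- 501
  mid <- 251
  vp <- viewpoint("cisC", (mid - 1) * 1000, mid * 1000)
  decay <- 2000 / (1 + abs(seq_len(n) - mid) / 5)
  sig <- grid_signals(pmax(0, decay + rnorm(n, sd = 20)))
  bg <- fit_cis_background(sig, vp)
  z <- zscores_cis(sig, bg)
  fitted_z <- z[match(bg$fit_idx, bg$cis_idx)]
  expect_lt(abs(mean(fitted_z)), 0.1)
  # hand formula on one region
  obs <- GenomicRanges::mcols(sig)$norm_rpm[bg$cis_idx[1]]
  expect_equal(z[1], (obs - bg$expected[1]) / bg$residual_sd)
})

test_that("trans z-scores use the global mean and SD", {
  # [1,1,1,1,6]: mean 2, sd sqrt(5); z(6) = 4/sqrt(5)
  vals <- c(1, 1, 1, 1, 6)
  gr <- c(grid_signals(vals[1:2], chrom = "cisC"),
          grid_signals(vals[3:5], chrom = "transC"))
  gr$region_id <- 1:5
  vp <- viewpoint("cisC", 10 * 1000 * 1000, 10 * 1000 * 1000 + 1000)
  z <- zscores_trans(gr, vp, exclusion_bp = 100, min_regions = 2)
  expect_equal(attr(z, "mean"), 2)
  expect_equal(attr(z, "sd"), sqrt(5))
  expect_equal(as.numeric(z), c(1 - 2, 1 - 2, 6 - 2) / sqrt(5))
  expect_equal(round(as.numeric(z)[3], 3), 1.789)
})

test_that("regions inside the exclusion zone change no trans z-score", {
  set.seed(42)
  base <- c(grid_signals(runif(40, 1, 5), chrom = "cisC"),
            grid_signals(runif(40, 1, 5), chrom = "transC"))
  base$region_id <- seq_along(base)
  vp <- viewpoint("cisC", 0, 1000)
  z1 <- zscores_trans(base, vp, exclusion_bp = 1e5)
  # add a huge-signal cis region within 100 kb of the viewpoint
  extra <- grid_signals(1e5, chrom = "cisC")
  GenomicRanges::ranges(extra) <- IRanges::IRanges(2001, 3000)
  extra$region_id <- length(base) + 1L
  z2 <- zscores_trans(c(base, extra), vp, exclusion_bp = 1e5)
  expect_equal(as.numeric(z1), as.numeric(z2))
  expect_error(zscores_trans(grid_signals(rep(5, 50), chrom = "transC"),
                             vp, exclusion_bp = 0), "SD is 0")
})

test_that("p-values are the upper normal tail", {
  expect_equal(pvalues_from_z(0), 0.5)
  expect_equal(pvalues_from_z(3), 0.00135, tolerance = 1e-2)
  expect_equal(pvalues_from_z(-2), 0.97725, tolerance = 1e-4)
  expect_error(pvalues_from_z(NaN))
})

test_that("q-values with pi0 = 1 are exactly Benjamini-Hochberg", {
  q <- qvalues(c(0.01, 0.02, 0.03, 0.04), pi0_method = "fixed")
  expect_equal(q$qvalue, rep(0.04, 4))
  expect_equal(qvalues(rep(1, 12))$qvalue, rep(1, 12))
  for (seed in 1:20) {
    p <- runif_pvalues(50, seed)
    expect_equal(qvalues(p, pi0_method = "fixed")$qvalue,
                 p.adjust(p, "BH"))
  }
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in sorted-p order and pi0 is sane", {
  set.seed(9)
  p <- c(runif(400), runif(100, 0, 1e-3))
  q <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q$qvalue[o]) >= -1e-12))
  expect_gt(q$pi0, 0.5)  # 80% of these p-values are null
  expect_lte(q$pi0, 1)
  expect_true(all(q$qvalue >= p * q$pi0 * 0 & q$qvalue <= 1))
})

test_that("conservative bounded p-values give pi0 = 1, not 0", {
  # all p in [0.5, 0.8]: stochastically larger than uniform, so the
  # true-null proportion cannot be estimated below 1; a naive bootstrap
  # would chase the bounded upper edge down to pi0 ~ 0 and declare
  # everything significant
  set.seed(55)
  p <- runif(500, 0.5, 0.8)
  q <- qvalues(p)
  expect_equal(q$pi0, 1)
  expect_equal(sum(q$significant), 0L)
})

test_that("interaction calling flags planted spikes and stays calibrated", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$spikes <- default_spikes(world$fm, cfg$vp)
  cfg$seed <- 301L
  sim <- simulate_3cseq(cfg, world$fm)
  sig <- sim_signals(sim$reads, world$fm, cfg$vp)
  set.seed(1)
  calls <- call_interactions(sig, cfg$vp)
  expect_s3_class(calls, "interaction_calls")
  expect_equal(order(calls$q, -abs(calls$z)), seq_len(nrow(calls)))
  spike_q <- calls$q[match(cfg$spikes$fragment_id, calls$id)]
  expect_gte(sum(spike_q <= 0.05), 16)
  out <- capture.output(print(calls))
  expect_match(out[1], "viewpoint", ignore.case = TRUE)
  s <- summary(calls)
  expect_equal(s$n_regions, nrow(calls))
})

test_that("calls are invariant under a global signal rescaling", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 302L
  sim <- simulate_3cseq(cfg, world$fm)
  sig <- sim_signals(sim$reads, world$fm, cfg$vp)
  set.seed(7)
  calls1 <- call_interactions(sig, cfg$vp)
  sig2 <- sig
  sig2$norm_rpm <- sig2$norm_rpm * 7.5
  set.seed(7)
  calls2 <- call_interactions(sig2, cfg$vp)
  expect_equal(calls1$z, calls2$z, tolerance = 1e-8)
  expect_equal(calls1$q, calls2$q, tolerance = 1e-8)
  expect_equal(calls1$id, calls2$id)
})

test_that("cis-only data is scored without trans output", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 303L
  sim <- simulate_3cseq(cfg, world$fm)
  sig <- sim_signals(sim$reads, world$fm, cfg$vp)
  cis_only <- sig[as.character(GenomicRanges::seqnames(sig)) == "chr1"]
  set.seed(1)
  calls <- call_interactions(cis_only, cfg$vp)
  expect_true(all(calls$is_cis))
  expect_gt(nrow(calls), 0)
})

test_that("stiffer smoothing increases residual variance", {
  world <- sim_world()
  cfg <- world$cfg
  cfg$seed <- 304L
  sim <- simulate_3cseq(cfg, world$fm)
  sig <- sim_signals(sim$reads, world$fm, cfg$vp)
  bg_soft <- fit_cis_background(sig, cfg$vp, spar = 0.06)
  bg_stiff <- fit_cis_background(sig, cfg$vp, spar = 0.4)
  expect_lte(bg_soft$residual_sd, bg_stiff$residual_sd)
})
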