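# Shared fixtures, built in code. The expensive pieces (simulated genome,
# fragment map) are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

# three-fragment toy chromosome: HindIII sites at 0-based 3 and 13
tiny_genome <- function() c(chrT = "GGGAAGCTTCCCCAAGCTTTT")

tiny_fm <- function() digest_genome(tiny_genome(), "AAGCTT")

# reads placed by explicit strand-aware 5' positions (1-based)
make_reads <- function(chrom, five_prime, strand = "+", width = 5L,
                       seqlengths = NULL) {
  five_prime <- as.integer(five_prime)
  strand <- rep_len(strand, length(five_prime))
  start <- ifelse(strand == "-", pmax(1L, five_prime - width + 1L),
                  five_prime)
  end <- ifelse(strand == "-", five_prime, five_prime + width - 1L)
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(five_prime)),
                               IRanges::IRanges(start, end),
                               strand = strand)
  gr$mapq <- rep(42L, length(five_prime))
  gr$five_prime <- five_prime
  if (!is.null(seqlengths)) GenomeInfoDb::seqlengths(gr) <- seqlengths
  gr
}

# default two-chromosome simulation world (10 Mb genome, HindIII),
# digested once per run
sim_world <- function() {
  if (!is.null(.fixture_cache$world)) return(.fixture_cache$world)
  cfg <- simulation_config(seed = 101L)
  genome <- simulate_genome(cfg)
  fm <- digest_genome(genome, cfg$site)
  .fixture_cache$world <- list(cfg = cfg, fm = fm,
                               sizes = GenomeInfoDb::seqlengths(fm))
  .fixture_cache$world
}

# run count -> normalize on a simulated read set, returning signals
sim_signals <- function(reads, fm, vp) {
  sig <- count_per_fragment(reads, fm)
  sig <- simple_rpm(sig)
  powerlaw_normalize(sig, fit_powerlaw(sig, vp = vp))
}

# uniform random background signals for q-value tests
runif_pvalues <- function(n, seed) {
  set.seed(seed)
  stats::runif(n)
}

# closed-form chi-square upper tail at even df = 2k:
# exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!
chisq_tail_even_df <- function(x, k) {
  i <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^i / factorial(i))
}
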