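# viewcall

Viewpoint-based interaction calling for 3C-seq / 4C-seq experiments.

3C-seq (one-vs-all chromosome conformation capture, equivalent to 4C-seq)
measures which genomic loci physically contact one chosen restriction
fragment — the *viewpoint*, typically a promoter or enhancer. The raw data
are aligned reads whose 5' ends mark captured ligation partners. Turning
them into a list of interacting regions requires dealing with two
confounders: unequal sequencing depth across heavy-tailed count
distributions, and the steep background decay of contact frequency with
genomic distance from the viewpoint. `viewcall` is for anyone analysing
viewpoint-anchored capture data who wants statistically scored interaction
calls, not just coverage tracks.

## The method

1. **Fragment map.** The genome is digested in silico at each occurrence
   of the enzyme site (e.g. HindIII `AAGCTT`); restriction fragments are
   the native resolution unit (~4 kb for a 6-cutter). Fixed windows
   (optionally overlapping) are the alternative counting grid.
2. **Counting.** Reads are assigned by strand-aware 5' position; the
   *informative-read* filter keeps only reads abutting restriction-site
   boundaries, the signature of genuine ligation junctions.
3. **Normalization.** The reverse-cumulative count distribution
   R(t) = #{regions with count ≥ t} is fitted in log–log space (counts
   < 50 and the viewpoint excluded) and every count is mapped onto a
   reference power law with exponent α = −1.35 and a 10⁶-read library:
   t′ = 10^((l + α̂·log₁₀ t − l_ref)/α), giving normalized RPM. A plain
   RPM normalization is also provided.
4. **Calling.** On the viewpoint chromosome, a cubic smoothing spline of
   signal versus distance (spar 0.1, range 0.06–0.4) estimates the
   expected background; each region is scored as **z = (obs − exp)/SD**
   with a single residual SD, p = 1 − Φ(z). Trans regions are scored
   against the global mean/SD (±100 kb around the viewpoint excluded).
   P-values become q-values via Storey FDR with bootstrap π0; calls are
   significant at q ≤ 0.05 (configurable).
5. **Replicates.** Union or intersection of per-replicate significant
   sets, values averaged, p-values combined by Fisher's method
   (X = −2Σln pᵢ ~ χ²₂ₖ), q-values recomputed. Intersection removes
   random-ligation artefacts, which rarely recur across libraries.
6. **Outputs.** Gene annotation (50 kb upstream / 5 kb downstream,
   strand-aware), bedGraph and TSV export, multi-scale domainogram
   matrices (2–30 kb windows), base-graphics plots.

A built-in simulator (`simulate_genome()` / `simulate_3cseq()`) generates
genomes and read sets with power-law distance decay, planted spike-in
interactions and uniform trans background, so the whole pipeline is
testable with known ground truth. See the methods vignette
(`vignettes/viewcall-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

Simulate a default library (two 5-Mb chromosomes, HindIII, 200,000 reads,
20 spiked interactions at 10× background, 50–500 kb from the viewpoint)
and call interactions:

```r
library(viewcall)
cfg <- simulation_config(seed = 42)
genome <- simulate_genome(cfg)
fm <- digest_genome(genome, cfg$site)     # 2,377 fragments
cfg$spikes <- default_spikes(fm, cfg$vp)
sim <- simulate_3cseq(cfg, fm)

sig <- count_per_fragment(sim$reads, fm)
sig <- simple_rpm(sig)
fit <- fit_powerlaw(sig, vp = cfg$vp)
print(fit)
#> Power-law reverse-cumulative fit
#>   slope    -0.8891   (reference alpha -1.35)
#>   offset    4.1132   (reference l_ref 5.4610, n0 1e+06)
#>   fitted on 369 regions with count >= 50
sig <- powerlaw_normalize(sig, fit)
set.seed(42)
calls <- call_interactions(sig, cfg$vp)
print(calls, n = 3)
#> Interaction calls for viewpoint chr1:2498000-2502000 (sim_viewpoint)
#>   2377 regions scored (1171 cis, 1206 trans); 19 significant at q <= 0.05
#>   pi0: cis 1.000, trans 1.000
#>   chrom   start     end  id  distance raw_count   rpm   signal         z
#> 1  chr1 2449625 2449863 516  -50256.0     11008 55040 4572.070 13.825704
#> 2  chr1 2548243 2552426 535   50334.5     10954 54770 4557.287 13.744057
#> 3  chr1 2396723 2402842 500 -100217.5      5373 26865 2850.844  9.630615
#> ...
```

Reading the output: the fitted slope (−0.89) describes this library's own
count decay; normalization maps it onto the α = −1.35 reference. Each row
is one restriction fragment with its distance to the viewpoint, raw and
normalized signal, and the z/p/q scores against the distance-decay
background. The top calls sit at planted spike positions (±50 kb, ±100 kb,
...); 19 regions are significant at q ≤ 0.05, all in cis — the sparse
uniform trans background is correctly not called. `plot(calls)` draws
signal versus distance with the spline background and significant calls
highlighted; `export_bedgraph()` / `export_text()` write browser tracks
and tables; `annotate_genes()` lists genes near the calls.

The same workflow runs from a shell:

```sh
Rscript inst/cli/viewcall.R simulate --seed 3 --out sim/
Rscript inst/cli/viewcall.R pipeline --genome sim/genome.fa \
    --bam sim/reads.bam --viewpoint chr1:2498000-2502000 --out run/
```

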