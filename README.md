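# orthoverlap

Cross-species tissue-enrichment overlap testing for bulk RNA-seq.

## The problem

A recurring question in comparative transcriptomics: genes enriched in a
tissue of species A — say, the sensory auricles of a planarian — were
selected by fold-change and p-value filters; an independent experiment in
species B (e.g. an RNAi knockdown) defined a second gene set. Do the two
sets share more orthologs than chance allows? `orthoverlap` implements
that analysis end to end for users who have replicate abundance matrices,
an OrthoFinder orthogroup table, and a target gene list:

1. **Enrichment filtering.** Counts are converted to TPM
   (TPM_g = 10⁶·(c_g/ℓ_g)/Σ_h(c_h/ℓ_h)); genes below a cumulative-TPM
   floor are removed; a two-sided Welch t-test on log₂(TPM + 1) and a
   group-mean fold change select the tissue-enriched set (defaults:
   fold ≥ 5, p ≤ 0.05, cumulative TPM ≥ 0.1).
2. **Orthology projection.** The orthogroup table is restricted to
   single-copy orthogroups (exactly one gene per species), which form the
   universe *N*; the enriched set (species A) and the target set
   (species B) are projected into orthogroup space.
3. **Overlap significance.** With *K* target orthogroups, *n* enriched
   orthogroups and observed overlap *k*, each of *B* Monte Carlo
   iterations draws *n* orthogroups uniformly without replacement and
   counts how many are targets; the corrected p-value is
   (#{null ≥ k} + 1)/(B + 1). The exact hypergeometric upper tail
   P(X ≥ k), X ~ Hypergeom(N, K, n), is reported alongside.
4. **Contamination screen.** Per transcript, the alien index
   AI = ln(E_in + 10⁻²⁰⁰) − ln(E_out + 10⁻²⁰⁰) from best in-group and
   out-group BLAST e-values flags likely contaminants at AI > 40.

A synthetic two-species generator (`simulate_two_species()`) with planted
enriched genes, a planted target set realising an exact overlap, and a
planted contaminant fraction provides ground truth for every stage.

## Worked example

```r
library(orthoverlap)
cfg <- synthetic_config(nb_dispersion = 0.02, replicates = 5,
                        planted_fold = 12, seed = 42)
sim <- simulate_two_species(cfg)
rep <- run_pipeline(sim$study, sim$orthogroups, sim$target,
                    blast = sim$blast, B = 10000, seed = 4242)
print(rep$overlap)
```

```
	Monte Carlo set-overlap test (sampling without replacement)

universe N = 1000, target K = 50, query n = 60, observed overlap = 20
null: 10000 iterations (seed 4242), expected overlap 3.00, max null overlap 10
iterations with overlap >= 20: 0
p (Monte Carlo, corrected) = 9.999e-05; raw = 0; exact tail = 1.744e-13
```

Reading this: of 1,000 single-copy orthogroups, 50 carry a target gene and
60 carry an enriched gene; 20 orthogroups carry both. Under the null the
expected overlap is 3 and the largest overlap seen in 10,000 random draws
was 10, so the observed 20 was never reached — the corrected Monte Carlo
estimate is 1/10001 ≈ 1e-4, and the exact tail (1.7e-13) shows how far
into the tail the observation sits. The pipeline recovered exactly the 20
planted overlap orthogroups, and the contamination screen recovered the
planted 5% contaminant fraction.

At the published study's scale (N = 8,682, K = 88, n = 430, k = 31,
B = 10,000) the same test yields zero exceedances and corrected
p ≈ 1e-4; the exact tail is ≈ 1e-16.

## Documentation

The methods vignette (`vignettes/overlap-methods.Rmd`) describes the
model, the filtering conventions and their boundary semantics, the null
and both p-value estimators, what the synthetic generator does and does
not emulate, and known limitations.
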