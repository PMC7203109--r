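# rbrid

Locate the RNA-binding region (RBR) of a protein from ±4SU crosslinking
proteomics (RBR-ID).

## The problem and the method

In an RBR-ID experiment, RNA is made photoactivatable with
4-thiouridine (4SU) and crosslinked to directly contacting protein by
312 nm UV. Crosslinked peptides acquire an RNA adduct and drop out of
the standard MS1 quantification, so peptides overlapping an RNA-binding
region are systematically **depleted** in +4SU runs relative to −4SU
controls. Comparing replicated ±4SU peptide intensity tables therefore
maps RNA contact sites onto the protein's primary sequence — this is how
the N-terminal RBR of the chromatin remodeler ATRX (a ~2492-residue
protein) was delimited.

`rbrid` implements the full analysis:

1. **Input** — peptide tables (generic TSV or MaxQuant `peptides.txt`),
   a run→(condition, replicate, batch) design TSV, protein FASTA;
   contaminant entries (`CON__`, `REV__`) are removed.
2. **Normalization** — each intensity is divided by the summed intensity
   of its MS run.
3. **Per-peptide statistics** — for each peptide with +4SU mean *m₊* and
   −4SU mean *m₋* (an all-zero condition mean is imputed as
   0.5 × the minimum observed positive condition mean):

   - depletion ratio: `log2(m₊ / m₋)` (negative ⇒ depleted),
   - *P* value: unpaired, two-sided pooled-variance Student *t* test
     across replicates,
   - **RBR-ID score** = `−log2(m₊/m₋) · (log10 P)²`,
   - significance: *P* < α (default 0.1) **and** depleted.

4. **Residue projection** — each residue gets the sum of the scores of
   all peptides overlapping it.
5. **Smoothing** — the residue track is smoothed with a from-scratch
   implementation of Friedman's variable-span *super smoother*
   (local linear fits at spans 0.05/0.2/0.5 of *n*, per-point span
   selection by smoothed leave-one-out residuals).
6. **Segment calling** — maximal runs of residues above a quantile
   threshold of the smoothed track, gap-merged and length-filtered,
   ranked by peak score.

A seeded synthetic-experiment generator (tryptic digestion of a random
protein, log-normal abundances, a planted RBR with multiplicative
depletion δ, log-normal noise, logistic intensity-dependent dropout,
8+8 replicates in 2 batches) provides ground truth for calibration and
recovery testing.

## Worked example

Simulate an experiment with a planted RBR at residues 1101–1400
(δ = 0.5, i.e. 2-fold depletion) on a 2500-residue protein, then run the
full pipeline on the written files:

```r
library(rbrid)
sim <- run_simulate("ex", seed = 7)
cfg <- rbrid_config(table = "ex/peptides.tsv", design = "ex/design.tsv",
                    fasta = "ex/protein.fa", out_dir = "ex/results")
report <- run_rbrid(cfg)

report$n_peptides_tested   # 139
report$n_significant       # 20
report$segments
#>   start  end peak_score mean_score
#> 1  1057 1413    19.6708   13.32221
unlist(recovery_metrics(report$segments, planted_rbr(1101, 1400, 0.5)))
#>      jaccard center_error     detected
#>    0.8403361   15.5000000    1.0000000
```

139 tryptic peptides are tested; 20 are significantly depleted
(*P* < 0.1 and negative log2 ratio), and the single called segment
(residues 1057–1413) recovers the planted region with Jaccard 0.84 and a
midpoint error of 15.5 residues. The top-scoring peptides sit inside the
planted region:

```r
st <- read.delim("ex/results/peptide_stats.tsv")
head(st[order(-st$score), c("peptide","log2_ratio","p_value","score","significant")], 3)
#>              peptide log2_ratio  p_value score significant
#> 67   VAQGLFANAQLAPLK     -1.217 8.00e-08  61.3        TRUE
#> 63       CVPQIAGDAFK     -1.031 1.61e-07  47.6        TRUE
#> 61 EVDLVVTYMVDEFDVPR     -0.944 6.35e-07  36.2        TRUE
```

`run_rbrid()` also writes `residue_profile.tsv` (per-residue raw and
smoothed scores), `segments.tsv`, a track plot `profile.png`, and a
`report.json` with stage counts. A thin command-line wrapper lives at
`inst/cli/rbrid.R` (`run`, `simulate`, and `smooth` subcommands).

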