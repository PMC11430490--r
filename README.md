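# mitoprofile

Characterization and pairwise comparison of circular mitochondrial
genomes.

Descriptive mitogenomics studies summarize a newly assembled vertebrate
mitochondrial genome — a circular ~16.5 kb molecule with 13
protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and a control region —
with a standard battery of statistics, and compare it base-by-base
against conspecific genomes. `mitoprofile` implements that battery as a
reusable, tested R package for anyone producing or reviewing such a
characterization:

* **Circular coordinate arithmetic**: 1-based inclusive feature tables,
  origin-spanning features as single wrapped records, strand-aware
  sequence extraction.
* **Gene accounting**: inventory by class, signed intergenic
  spacer/overlap table with the conservation law
  Σ lengths + Σ signed gaps = L.
* **Composition**: base counts, A+T content, and the strand-asymmetry
  statistics AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C), per
  region and in circular sliding windows.
* **Codon usage** under the vertebrate mitochondrial code (NCBI
  table 2: TGA→Trp, ATA→Met, AGA/AGG→stop): codon counts, RSCU
  (RSCU(c) = k·n\_c / Σ n, summing to family size k), amino-acid
  frequencies, start/stop-codon classification including incomplete
  (`T`/`TA`) stops.
* **Control region**: motif occurrence counting (overlapping or greedy)
  and exact maximal tandem-repeat detection.
* **Pairwise comparison**: anchored rotation, banded global alignment
  with affine gaps, left-normalized variant calling
  (substitution/insertion/deletion), codon-level consequence annotation
  (synonymous / missense / frameshift / inframe / rna / noncoding), TSV
  and minimal-VCF output.
* **Synthetic data**: a generator that realizes a published gene layout
  exactly (the default is the 16,541 bp douc langur arrangement with its
  1,094 bp origin-spanning control region and 22 bp atp8/atp6 overlap)
  with tunable A+T content, plus implanted-mutation plans with exact
  truth sets, so the whole pipeline is testable offline.

## Worked example

```r
library(mitoprofile)

# the published 37-gene feature table (plus control region) as input
ann <- read_feature_table(
  system.file("extdata", "douc_features.tsv", package = "mitoprofile"),
  16541)
summarize_inventory(ann)
#> InventorySummary: 38 features on 16541 bp
#>   PCG 13 (11292 bp, 68.27% of genome)  tRNA 22 (59-75 bp)  rRNA 2  CR yes
```

13 PCGs spanning 11,292 bp are 68.27% of the genome; tRNAs range 59–75 bp.
The spacer table reproduces every printed intergenic value, e.g. the 2 bp
trnV/rrnL overlap:

```r
head(as.data.frame(spacer_overlap_table(ann)), 4)
#>   upstream_name downstream_name gap
#> 1          trnF            rrnS   0
#> 2          rrnS            trnV   0
#> 3          trnV            rrnL  -2
#> 4          rrnL           trnL2   0
```

Generate a synthetic genome realizing that layout, implant a known set of
mutations, and recover them:

```r
sim <- generate_genome(default_layout(), at_target = 0.614, seed = 42)
skew_profile(sim$genome$residues, "whole_genome")
#> whole genome: AT% 61.40  AT-skew -0.02619  GC-skew -0.02803

mut <- mutate_genome(sim$genome, sim$annotation,
                     mutation_plan(30, 4, 9, seed = 7))
cmp <- compare_genomes(sim$genome, sim$annotation, mut$genome)
cmp$summary
#> DiffSummary: 43 variants (30 substitutions, 4 insertions, 9 deletions);
#>   24 amino-acid-changing position(s)
score_recovery(cmp$variants, mut$truth)[c("precision", "recall")]
#> $precision [1] 1    $recall [1] 1
```

All 43 implanted events are recovered exactly (position, type and
alleles), and applying the called variants to the reference reconstructs
the mutated genome byte-for-byte.

A command-line wrapper is included for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mitoprofile.R",package="mitoprofile"))')" \
  characterize genome.fasta features.tsv --out reports/
```

with `compare` and `simulate` subcommands mirroring the functions above.

## See also

The methods vignette (`vignettes/mitoprofile-methods.Rmd`) documents the
statistical definitions, coordinate conventions, alignment scoring and
normalization, the generator's design and its limits, and the default
parameter choices.
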