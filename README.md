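# linctools

Discovery and characterization of large intergenic noncoding RNAs
(lincRNAs) from assembled transcriptomes.

LincRNAs are transcripts longer than 200 nt expressed from regions that
do not overlap protein-coding genes. Cataloguing them from multi-tissue
RNA-seq takes a chain of downstream decisions — which assembled models
are reliably expressed, which overlap known annotation, which look
coding, which are structurally and positionally credible — followed by
characterization of the survivors. `linctools` implements that chain
for analysts who already have assembled transcript models (GTF/BED12)
and per-tissue FPKM, and who want a reproducible, testable catalog plus
its standard companion analyses. A seeded synthetic-data generator with
planted ground truth backs every stage, so the whole pipeline is
verifiable end to end without any external data.

## What it computes

**Identification** — a five-step filter cascade with a telescoping
attrition ledger:

1. expression support (max-tissue FPKM and mean coverage thresholds),
2. exon-level overlap exclusion against coding / known-noncoding /
   pseudogene catalogs (strand-blind, intronic transcripts survive),
3. alignment-free coding-potential classification,
4. structure (>1 exon, length strictly > 200 nt),
5. intergenic position (≥ 1 kb from any coding gene).

Survivors are merged into loci by intron-chain identity (a "full"
reconstruction match is an identical intron chain; "partial" is a
shared intron or ≥ 1 bp same-strand exon overlap) and can be combined
with a documented lincRNA catalog, deduplicating overlapping loci.

**Coding potential** — a classifier over *adjoining nucleotide
triplets*: a 64×64 log-odds table
`log2(P_coding(t_j | t_i) / P_noncoding(t_j | t_i))` of transitions
between consecutive non-overlapping triplets, scored per reading frame
by the maximal-scoring contiguous segment (Kadane), best frame wins,
with a threshold calibrated on training scores.

**Characterization** —

- Jensen–Shannon tissue specificity,
  `JS = max_t (1 − sqrt(JSD(p, δ_t)))` with entropies in bits, called
  specific at JS ≥ 0.5;
- replicate recurrence (max over tissues of within-tissue replicate
  hits at match level ≥ partial);
- TSS-centered histone metagene profiles with exact per-bin integrals
  and stratified random intergenic controls;
- "two-color" co-expression networks (|r| ≥ 0.9 on log2(FPKM+1)),
  Markov clustering (inflation 1.8, implemented from scratch),
  hypergeometric GO enrichment with BH correction over modules of ≥ 6
  genes, and lincRNA function inheritance;
- nearest-coding-neighbor correlation with the r ≥ 0.8 cutoff and a
  10,000-pair randomized GO-sharing null.

## Worked example

Simulate the default study — six tissues × six replicates, 50 coding
genes, 20 planted novel lincRNAs, assembly dropout 0.1, intronic and
exon-truncation noise — and run the cascade:

```r
library(linctools)

st  <- simulate_study(seed = 7)
res <- run_pipeline(st$merged, st$fpkm, st$coverage, st$sequences,
                    st$catalogs, st$model, st$config)
res$ledger
#>                  step  n_in n_out n_eliminated
#> 1:         expression   278   192           86
#> 2: annotation_overlap   192    67          125
#> 3:   coding_potential    67    67            0
#> 4:          structure    67    20           47
#> 5:         intergenic    20    20            0
```

278 merged assembly transcripts enter; low-FPKM/low-coverage noise
falls at step 1, everything touching annotated exons (including the
assembled coding transcripts themselves) at step 2, and single-exon
intronic fragments at step 4, leaving a 20-transcript catalog. Checking
it against the planted truth:

```r
planted <- tx_subset(st$truth$annotation, st$truth$planted_lincrna_ids)
rec <- match_against(planted, res$catalog)
#> recovered 20 / 20 planted lincRNAs (all at level "full")

sc <- specificity_scores(st$expr$fpkm[st$truth$planted_lincrna_ids, ])
head(sc, 3)
#>    transcript_id  js_score argmax_tissue defined is_specific
#> 1:    LINC0001.1 0.7772048         heart    TRUE        TRUE
#> 2:    LINC0002.1 0.8760749        thymus    TRUE        TRUE
#> 3:    LINC0003.1 0.7937335          lung    TRUE        TRUE
sum(sc$is_specific)
#> [1] 10
```

All 20 planted lincRNAs are recovered with identical intron chains, no
false positives, and exactly the planted half of them score as
tissue-specific (a transcript with ~94% of its mass in one tissue
scores ≈ 0.78–0.88; the uniform six-tissue pattern scores ≈ 0.19).

A thin command-line front end over the same functions lives in
`inst/scripts/linctools-cli.R` (subcommands `simulate`, `classify`,
`specificity`, `recurrence`, `histone-profile`, `modules`, `neighbors`,
`annotate`), each writing TSV/GTF outputs plus a JSON manifest of
config, seed, input digests and stage counts.

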