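# pairiso

Full-length transcript-isoform identification and quantification in single
cells from **paired short-read end-capture libraries**: one library samples
transcription start sites (TSS), the other transcription end sites (TES),
and every read carries a cell barcode (CB) and a unique molecular
identifier (UMI). Short reads cannot span a transcript, but the *pair* of
end observations plus the splice junctions covered by the reads of the same
molecule pin down which annotated isoform that molecule came from.

The package is aimed at method developers and analysts working with
end-capture single-cell protocols who need a self-contained, testable
implementation of the computational pipeline: read-structure parsing,
UMI collapsing, annotation-guided isoform assignment, spike-in
benchmarking, and downstream splicing statistics — all runnable on
synthetic data without external sequencing data or an aligner.

## The method

For each UMI group *u* (all aligned fragments sharing `(CB, gene, UMI)`),
the **compatibility set** is

C(u) = { t ∈ isoforms(gene) :
  |tss_t − obs5(u)| ≤ τ  (if a TSS-library fragment is present),
  |tes_t − obs3(u)| ≤ τ  (if a TES-library fragment is present),
  J(u) ⊆ J(t), and no block of u overlaps an intron of t }

where `obs5`/`obs3` are the strand-aware outermost termini observed in the
TSS/TES libraries, `J(u)` the splice junctions implied by split
alignments, and τ an end-matching tolerance (default 50 bp).

* |C(u)| = 1 → **direct** assignment.
* |C(u)| > 1 → **maximal-probability rescue**: the UMI is assigned to
  argmax over C(u) of `(n_direct(t) + 1)`, where `n_direct(t)` counts the
  gene's directly assigned UMIs pooled across cells (pseudocount 1;
  ties break to the lexicographically smallest transcript id).
* |C(u)| = 0 → unassigned (tallied, never counted).

Counts accumulate in a sparse isoform × cell matrix with per-entry
direct/probabilistic provenance. Downstream, the package classifies
alternative-splicing events between isoform pairs (AP, APA, SE, RI, MXE,
A3SS, A5SS), runs Wilcoxon rank-sum differential tests at the standard
thresholds (isoforms: |log2FC| > 0.25, BH-adjusted p < 0.05; accessibility
peaks: |log2FC| > 0.1, raw p < 0.0005), annotates peaks to promoter
windows (TSS −2000/+200, strand-aware), and measures the fraction of
splicing sites whose ±100 bp windows overlap differentially accessible
regions.

## Worked example

The built-in simulator generates a SIRV-like annotation (69 isoforms over
7 multi-isoform genes) plus a 92-species ERCC-like 2-fold abundance ladder,
per-cell molecules with CB+UMI, raw FASTQ reads in either library dialect,
and pre-aligned SAM records (the package consumes alignments; it does not
align).

```r
library(pairiso)
ann <- make_synthetic_annotation(seed = 11)           # 69 + 92 transcripts
mol <- simulate_molecules(ann, n_cells = 3, depth_scale = 0.5, seed = 11)
al  <- emit_alignments(mol, ann)
res <- run_pipeline(al$tss_sam, al$tes_sam, ann$transcripts)
print(res)
#> pipeline_result: 31852 fragments -> 7094 UMI groups
#>   (7094 direct, 0 probabilistic, 0 unassigned)

eval_report(unique(mol$transcript_id), res$matrix, res$assignments, mol,
            abundance_truth = ann$truth[ann$truth$class == "ercc"],
            indistinguishable = res$index$indistinguishable)
#> EvalReport
#>   detected 115 / 115 isoform units (sensitivity 1.000)
#>   per-UMI feature accuracy 1.0000
#>   expected-vs-observed r = 0.9902
```

Every simulated UMI is assigned directly and correctly (the noise-free
full-coverage case), every isoform that received at least one molecule is
detected, and quantified ladder totals track expected abundances with
r = 0.99 on the log2 scale.

The same steps are scriptable from the shell:

```sh
pairiso sim    --out demo --cells 3 --seed 11
pairiso tag    --fastq demo/tss.fastq --end tss --out demo/tagged.fastq
pairiso assign --tss demo/tss.sam --tes demo/tes.sam \
               --gtf demo/annotation.gtf --out demo/mtx
pairiso eval   --matrix demo/mtx --truth demo/molecules_truth.tsv \
               --abundance demo/abundance_truth.tsv \
               --gtf demo/annotation.gtf --out demo/eval.json
```

(`pairiso` is installed under `<library>/pairiso/exec/pairiso`.)

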