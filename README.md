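# bimodalTF

Transcription factors (TFs) in embryonic stem cells bind far more of the
genome than their consensus motifs explain. `bimodalTF` is an R package for
dissecting sequence-dependent TF–DNA binding specificity into three
contributions — local GC-content, specific k-mers, and short tandem repeats —
and for modeling how a cooperatively binding factor can take over GC-rich
DNA from a competitor purely through its concentration. It is aimed at
computational biologists analyzing ChIP-seq-style peak sets (BED) against a
genome (FASTA), and it ships a synthetic-data generator so the entire
pipeline runs and is tested without downloading any external data.

## The models

**Peak-over-background k-mer energy.** For a k-mer *s*, the statistical
binding energy in units of k<sub>B</sub>T is

    U_k(s) = -ln( (<N_k(s)>_peak + 1) / (<N_k(s)>_background + 1) )

where `<N>` is the mean count of *s* plus its reverse complement per 100-bp
peak-center (or background) window, palindromes counted once. A sequence is
scored by its free energy, `F_k = -ln Σ_i exp(-U_k(s_i))` over all
k-windows; lower F = more peak-like. Classification performance is the
tie-corrected Mann–Whitney ROC AUC, and the k-mer specificity of a peak
group is `ΔAUC = max_k AUC(k) − AUC(1)`, which subtracts the GC-content
contribution (k = 1 scores by composition alone). Comparing ΔAUC between
GC-poor (GC < 0.4) and GC-rich (GC > 0.6) peaks separates motif-driven from
composition-driven binding.

**Pair correlations.** Repeat structure is measured by
`η_αβ(x) = (N_αβ(x) − <N_αβ(x)>_rand) / L`, the excess of (α, β) nucleotide
pairs at separation x over a composition-preserving shuffled null (100
shuffles per sequence, or its exact closed-form expectation). `η_CC(6)`
detects the `[CNNNNNC]` periodicity of GC-rich bound regions; `η_AA(1)`
etc. detect poly(A)/poly(T)/poly(C)/poly(G) (antinucleosomal) tracts.

**TSS metaprofiles.** GC-content and binding intensity aligned around
transcription start sites (50-bp sliding window, 10-subgroup error bars),
bound/unbound TSS classification, joint GC × log-distance histograms, and
4-kb methylation metaprofiles normalized per CpG site.

**Competitive binding equilibrium.** Myc-Max heterodimer binds high-GC
(`DNAH`) and low-GC (`DNAL`) DNA; two DNA-bound heterodimers form a bivalent
heterotetramer on DNAH only; Smad1 binds both classes as a homodimer.
Mass-action equilibrium with K1 = 145 nM, K2 = 90 nM, K_L = 500 nM,
K̃_H = 1e-14 M², K̃_L = 2.5e-14 M² is solved exactly (DNA species eliminated
analytically, nested root bracketing on the two conservation equations) and
swept over total Myc. The cooperative tetramer produces a sharp
concentration-driven switch of DNAH occupancy from Smad to Myc that the
heterodimer-only control lacks.

## Worked example

```r
library(bimodalTF)

# synthetic study conditions: bimodal peak GC, motif planted in low-GC peaks
spec <- synthetic_spec(seed = 1)
g  <- generate_genome(spec)
gp <- generate_peaks(spec, g)

res <- stratified_specificity(gp$peaks, gp$genome$sequences, seed = 1)
res$low
#> specificity_summary: synthTF/ESC, low-GC stratum, 1445 peaks, dAUC=0.2702
#>      1      2      3      4      5      6      7      8
#> 0.6156 0.7155 0.7798 0.8361 0.8634 0.8810 0.8844 0.8858
res$high
#> specificity_summary: synthTF/ESC, high-GC stratum, 1397 peaks, dAUC=0.0506
#>      1      2      3      4      5      6      7      8
#> 0.5256 0.5208 0.5188 0.5178 0.5190 0.5289 0.5620 0.5762
```

Low-GC peaks carry the planted motif, so AUC climbs steeply with k
(ΔAUC = 0.27): binding there is k-mer-specific. High-GC peaks differ from
their backgrounds only weakly beyond composition (ΔAUC = 0.05). This is the
bimodal-specificity signature the package quantifies.

```r
p <- equilibrium_parameters(Myc_tot = 1e-6)   # 1 uM total Myc
solve_equilibrium(p)
#> equilibrium_state (M):
#>         Myc        Smad        DNAH        DNAL    Myc_DNAH  Myc_DNAH_2
#> 5.36647e-07 2.25374e-07 2.75319e-08 1.21802e-07 1.01896e-07 1.15364e-07
#>    Myc_DNAL  Smad2_DNAH  Smad2_DNAL
#> 1.30729e-07 1.39844e-07 2.47469e-07
#> max |relative residual| = 1.06e-15
```

At 1 uM Myc, most high-GC DNA is Myc-bound (heterodimer + tetramer) and
Smad is pushed toward low-GC DNA; sweeping `Myc_tot` down four-fold with
`sweep_myc_total()` reproduces the sharp hand-off of high-GC occupancy back
to Smad, and `robustness_scan()` shows the tetramer model stays sharper than
the heterodimer-only control under tenfold perturbations of every constant.

`run_pipeline(default_pipeline_config(seed = 1))` executes every stage
(GC distributions → k-mer specificity → repeat correlations → TSS and
methylation profiles → equilibrium sweeps) and writes TSV outputs plus a
reproducibility manifest.

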