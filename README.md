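# cfdecon

Fragment-level tissue-of-origin analysis for plasma cell-free DNA
(cfDNA) methylation sequencing.

Dying cells shed short DNA fragments into blood plasma. Because DNA
methylation is tissue specific, the joint methylation state of the CpG
sites on a *single sequenced fragment* identifies where that fragment
came from — which makes cfDNA a non-invasive window on tumor load and
tissue damage. cfdecon takes standard Bismark-style bisulfite outputs
and answers two questions:

1. **How much of this plasma cfDNA is tumor-derived?** (tumor burden θ)
2. **Which tissues is this cfDNA coming from, in what proportions?**
   (tissue fractions, with an explicit *unknown* class)

## The model in brief

A marker region's methylation level in class *c* is
p ~ Beta(α<sub>c</sub>, β<sub>c</sub>); the *n* CpG states on one
fragment are i.i.d. Bernoulli(p) given p. The marginal likelihood of a
fragment with *k* methylated CpGs under class *c* is the closed form

&nbsp;&nbsp;&nbsp;&nbsp;P(frag | c) = B(α<sub>c</sub>+k, β<sub>c</sub>+n−k) / B(α<sub>c</sub>, β<sub>c</sub>).

Tumor burden maximizes the two-class mixture log-likelihood
Σ<sub>i</sub> log[θ·L<sub>t,i</sub> + (1−θ)·L<sub>n,i</sub>] over
θ ∈ [0, 1] (grid search, step 10⁻⁴, ties toward 0). Multi-tissue
composition assigns each fragment to its maximum-likelihood class only
when the top-two likelihood ratio is ≥ a fold-change threshold (default
2); otherwise the fragment counts as *unknown*. Fractions including
unknown sum to 1.

## Worked example

Simulate a known three-tissue plasma (10% liver, 20% lung, 70% blood),
write it out in the Bismark-style dialects, ingest it back, and
deconvolve:

```r
library(cfdecon)

cfg <- multi_tissue_config(c(liver = 0.1, lung = 0.2, blood = 0.7),
                           n_fragments = 5000, seed = 7)
sim <- simulate_fragments(cfg)
files <- emit_bismark_dialect(sim, "demo", conflict_rate = 0.02)

frags <- ingest_fragments(files$reads, files$calls_ot, files$calls_ob)
frags[1:3, ]
#>    fragment_id  chrom start   end length n_cpg      methState
#> 1:     S004551   chrS     5   171    166    14 11111111111111
#> 2:     S002260   chrS    10   186    176    11    00010000000
#> 3:     S003778   chrS    10   207    197    13  1000001011011

cf_deconvolve(frags, sim$markers, fold_change = 2)
#> cfDNA deconvolution over 5000 fragments (fold change >= 2):
#>   liver           560 fragments  0.1120
#>   lung           1009 fragments  0.2018
#>   blood          3376 fragments  0.6752
#>   unknown          55 fragments  0.0110
```

Each row of the fragment table is one cfDNA fragment; `methState` is
its joint methylation string (`1` methylated, `0` unmethylated, genomic
order). The recovered fractions sit within ~1 point of the simulated
truth, and 1.1% of fragments were too ambiguous to call and are
reported as `unknown` rather than redistributed.

Tumor burden on a two-class world (tumor markers Beta(8,2) vs normal
Beta(2,8), true θ = 0.05):

```r
sim2 <- simulate_fragments(two_class_config(0.05, n_fragments = 5000, seed = 8))
cancer_detector(sim2$fragments, sim2$markers)
#> tumor burden theta = 0.0516 (log-lik -14286.697, 5000 fragments used, 0 trimmed)
```

## Command line

Every step is a subcommand of one entry point (`cfdecon_cli()`), each
writing tab-delimited outputs plus a JSON run manifest:

```sh
Rscript -e 'quit(status = cfdecon::cfdecon_cli())' demo --outdir out --seed 7
Rscript -e 'quit(status = cfdecon::cfdecon_cli())' cancer-detector \
    --fragments frags.tsv --markers markers.tsv --output burden.tsv
```

`demo` runs the full loop — simulate, emit, ingest, fit, deconvolve,
estimate burden, draw the fraction pie chart — in under a minute.
Subcommands: `merge-pe`, `merge-cpgs`, `frag-meth`, `marker-params`,
`intersect`, `cancer-detector`, `cf-deconvolve`, `plot`, `simulate`,
`demo`.

## Documentation

The methods vignette
(`vignettes/cfdna-deconvolution-methods.Rmd`) describes the model and
its assumptions, the synthetic world and what green tests do and do not
establish, numerical choices, and known limitations.
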