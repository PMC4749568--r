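# sigold

Serial-multiplex immunogold labeling (siGOLD) assigns molecular identities
to neurons in serial-section TEM connectomes: small subsets of the
thousands of 40-nm sections are each immunogold-labeled with one
neuropeptide antibody, and because neuropeptides fill the whole axon inside
dense-core vesicles (DCVs), a neurite that labels strongly on a few sparse
sections can be traced through the entire series and tagged with that
identity — together with every synapse it makes.

`sigold` is an R package for designing and analysing such experiments. It
is aimed at connectomics groups who want to (a) quantify and call
identities from gold-count tables, (b) ask *before cutting grids* how many
runs of how many sections a labeling design needs, and (c) analyse the
circuits of the identified neurons. It provides:

* a generative simulator of serial-section immunogold datasets — bilateral
  neurite populations, bursty per-section DCV occupancy (two-state Markov
  chain with Poisson counts), sparse run-structured labeling designs, and a
  thinned-Poisson gold-deposition law
  `N_obs ~ thin( Poisson(alpha * D * S[a,p] + lambda_bg * A), p_enh )`
  with antibody cross-reactivity `S`, background `lambda_bg`, and
  incomplete silver enhancement `p_enh`;
* gold scoring: antibody x layer x neurite tables with totals, the >= 2
  gold candidate rule, control-transect sampling, intensity shading, and a
  DCV co-occurrence QC check;
* rule-based identity calling (candidate vs confirmed across paired
  grids), coexpression detection, cross-reactive antibody-group flagging,
  bilateral-symmetry scoring, and replicate-based power analysis of
  labeling designs (precision / recall / F1 against simulated ground
  truth);
* circuit reconstruction from SWC skeletons and connector tables: directed
  synapse-count graphs (edge width proportional to the square root of the
  synapse count), in-degree spectra, laterality indices, and
  vesicle-diameter synapse classification (DCV ~63 +- 8.4 nm vs clear
  ~35 nm, cut at 45 nm);
* groupwise unbiased average-template construction for image stacks by
  iterative register-rank-average cycles (affine then affine+deformable,
  keep the 24 most similar of 36 by normalised cross-correlation).

All user-facing functions take data frames first and return tibbles, with
`tidy()` / `glance()` / `autoplot()` methods for the result objects, plus a
thin command-line wrapper (`inst/cli/sigold.R`) over the same functions.

## Worked example

Simulate a study-like experiment (11 antibodies, two ~5-section runs per
antibody ~50 sections apart, 200 neurites over 200 sections), call
identities, and check bilateral symmetry:

```r
library(sigold)

cfg <- sim_config(n_neurites = 200, seed = 11)
ds  <- generate_dataset(cfg)
ds
#> <sigold_dataset>
#>   200 neurites (66 peptidergic) over 200 sections
#>   design: paired-grids, 110 labeled sections
#>   gold cells: 22000; synapses: 120

calls <- call_identities(ds$gold, ds$design, dcv = ds$dcv)
glance(calls)
#> # A tibble: 1 x 6
#>   n_calls n_candidate n_confirmed n_neurites n_coexpressing n_dcv_absence_flags
#>     <int>       <int>       <int>      <int>          <int>               <int>
#> 1      62           3          59         62              0                  15

head(tidy(calls), 2)
#> # A tibble: 2 x 8
#>   neurite_id antibody tier      max_count n_runs_hit total_gold witness_layers
#>   <chr>      <chr>    <chr>         <int>      <int>      <int> <chr>
#> 1 n1         RYa      confirmed         4          2         22 6;8;9;60;62;63
#> 2 n103       LUQ      confirmed         3          1          8 82;84

bilateral_symmetry_score(calls, ds, radius_um = 1)
#> [1] 0.8813559
```

62 of the 66 truly peptidergic neurites are recovered; most are confirmed
on both grids of their antibody pair, 15 carry the
`dcv_absence_false_negative` flag (their silent partner run falls on
sections that genuinely lack DCVs), and the confirmed positives mirror
left/right at 88% within 1 um.

The packaged fixture of published gold counts (PDF antibody, 35
nuchal-organ sensory neurons, layers 703/723/787) works the same way:

```r
tab <- load_table2_fixture()
select_candidates(tab, min_gold = 2)$neurite_id
#>  [1] "l12" "l13" "l14" "l2"  "l6"  "l7"  "l8"  "r1"  "r12" "r13" "r4"  "r6"
#> [13] "r8"
```

i.e. 13 of the 35 neurons carry at least one section with two or more gold
particles — these are the profiles one would select for full tracing.

Design power analysis before committing grids:

```r
ev <- evaluate_design(sim_config(n_neurites = 200),
                      tibble::tibble(runs_per_antibody = c(1, 2),
                                     sections_per_run  = c(1, 5)),
                      n_replicates = 20, seed = 1)
tidy(ev)        # mean precision / recall / F1 with Monte-Carlo SEs
autoplot(ev)    # recall & precision across the design sweep
```

See `vignettes/sigold-methods.Rmd` for the models, their assumptions, all
tunable parameters and the package's numerical choices.

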