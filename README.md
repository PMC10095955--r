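# fernquant

Quantitative analysis of apical-cell (AC) driven growth in fern
gametophytes from two-timepoint membrane-stain microscopy, paired with a
synthetic prothallus simulator that makes every stage of the analysis
testable without real confocal data.

Gametophytes of some ferns keep a single wedge-shaped apical cell at the
apical notch. The AC renews itself by an oblique division and, with its
two trapezoid progenies, forms a conserved three-celled packet; one
48-hr round (oblique division plus a periclinal/anticlinal division in
the adjacent trapezoid) yields five packet cells. The analysis asks
whether the small cells at the apical centre divide more or expand less,
using three statistics computed per gametophyte over a 48-hr interval:

- percentage of cells that divided:
  `100 · n_divided / n_cells_at_0hr` (per group),
- relative total cell area: `100 · area_48hr(daughters included) / area_0hr`,
- per-cell relative growth: `(A_48(total) − A_0) / A_0`,

compared between the *centre of the meristem* (the AC, its packet
progenies and their surrounding cells) and all other non-trichome cells,
with pooled two-tailed Student *t*-tests across samples.

The package provides:

- `simulate_gametophyte()` — a polygonal tissue simulator (power-diagram
  tessellation, oriented chord-split divisions, region-dependent
  stochastic division and lognormal growth) with per-cell ground truth;
- `render_image_pair()` — membrane-stain-like image pairs with
  ground-truth label masks and lineage tables;
- `segment_image()` (`preprocess_smooth`, `extract_markers`,
  `watershed_segment`, `measure_cells`) — marker-based watershed
  segmentation by h-minima markers and seeded flooding;
- `track_pair()` (`register_frames`, `register_similarity`,
  `match_overlap`, `classify_divided`) — similarity registration and
  overlap-based lineage matching with division calling;
- `define_centre_group()`, `pct_divided()`, `relative_total_area()`,
  `relative_cell_growth()`, `student_t_two_tailed()`,
  `render_value_map()` — the group quantification;
- `run_pipeline()` / `run_recovery_experiment()` — end-to-end
  orchestration and the parameter-recovery experiment;
- a thin command-line front end in `inst/cli/fernquant.R`
  (`simulate`, `segment`, `track`, `quantify`, `run`, `recover`).

## Worked example

Simulate one gametophyte at the default study conditions (60 cells, one
48-hr round, published division/growth rates), run the full pipeline on
the rendered pair, and read off the per-sample statistics:

```r
library(fernquant)
params <- simulation_params(seed = 42)
cfg <- pipeline_config(list(seed = 42, simulate = list(params = unclass(params))))
res <- run_pipeline(cfg)
res$stats
#>   n_centre n_outside mean_area_centre_0 mean_area_outside_0 pct_div_centre
#> 1        8        52              103.9               387.2             25
#>   pct_div_outside rel_area_centre rel_area_outside
#> 1           19.23           157.7            131.3
```

The centre group holds 8 cells averaging 104 µm² against 52 outside
cells averaging 387 µm² — the apical size gradient. Single samples are
noisy (8 centre cells make the division percentage jump in 12.5-point
steps); the across-sample experiment is the meaningful readout:

```r
rec <- run_recovery_experiment(seed = 1, n_samples = 8,
                               use_segmentation = FALSE)  # ground-truth path
rec
#> fq_recovery: 8 samples
#>             statistic   mean    se n
#> 1  mean_area_centre_0 104.70 4.808 8
#> 2 mean_area_outside_0 424.08 7.205 8
#> 3      pct_div_centre  50.05 5.738 8
#> 4     pct_div_outside  16.00 1.388 8
#> 5     rel_area_centre 152.49 3.824 8
#> 6    rel_area_outside 131.82 0.707 8
#> t-tests: % divided p = 4.87e-05, relative area p = 0.000109
```

Eight simulated gametophytes recover the generating rates (centre cells
divide at ~46% vs ~15% outside; relative areas ~158% vs ~132%) within
sampling error, and both centre-vs-outside contrasts reject strongly —
the size gradient at the apex reflects division activity, not reduced
expansion. `use_segmentation = TRUE` (the default) runs the same
experiment through rendering, watershed segmentation and lineage
tracking instead of the ground-truth ledger.

## Documentation

The methods vignette (`vignettes/fernquant-methods.Rmd`) describes the
tissue model, the segmentation and tracking algorithms and their
parameters, the statistical calibration, the design decisions taken
where the protocol is underdetermined, and what passing synthetic-data
tests do and do not imply about real micrographs.
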