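# palynet

Hierarchical pollen-image classification with calibrated abstention, plus
the downstream stratigraphic statistics of palynology — in one desk-scale,
fully reproducible R package.

## The problem

Reconstructing past vegetation from lake-sediment cores means identifying
hundreds of fossil pollen grains per sample under a microscope. palynet
automates that identification step and everything after it:

* **Taxonomy-tree classifiers.** Small convolutional networks (a frozen
  transfer front block, a shared VGG-style core in shallow and deep
  variants, a dropout softmax head) are arranged along a configurable
  taxonomy. The default tree has seven nodes: a main morphotype classifier
  (aporate Juniperus/Thuja, vesiculate Abies/Picea and Pinus groups,
  triporate and tricolpate mixes, NPP/minerals), genus-level nodes beneath
  it, and species-level Alnus and Acer nodes — 14 terminal classes.
* **Calibrated abstention.** Each node's confidences are calibrated by
  temperature scaling (a scalar *T* > 0 fitted by minimizing validation
  negative log-likelihood; the argmax, hence accuracy, is unchanged). A
  grain whose best calibrated confidence falls below τ = 0.7 abstains: to
  `Unknown` at the root, to the parent taxon deeper down — an indecisive
  Acer-node prediction still counts as Acer, as an analyst would record it.
* **Paleo analytics.** Exotic-marker concentration
  (`pollen × dose / (marker × volume)`), influx (concentration ÷ local
  deposition time from an age–depth model), percentage diagrams under a
  configurable pollen-sum policy, CONISS (stratigraphically constrained
  incremental sum-of-squares clustering) and broken-stick selection of the
  number of significant biozones.
* **A synthetic slide generator.** Parametric dark-field renderings of all
  14 classes (sacci, pores, arci, furrows, bubbles, mineral shards — each
  with logged ground-truth geometry) and a tunable fresh→fossil
  degradation dial, so the entire pipeline is testable end to end with no
  proprietary image corpus.

## Worked example

Train and evaluate the full seven-node hierarchy on the synthetic preset
(about ten minutes on one CPU):

```r
library(palynet)

cfg     <- run_config(seed = 11)      # 200 images/class, desk-scale epochs
gen     <- cmd_generate(cfg)          # render + 75/15/10 split
trained <- cmd_train(cfg, gen)        # train 7 nodes, calibrate on validation
ev      <- cmd_evaluate(cfg, trained) # classify the held-out test split

ev$confusion
#> <confusion_apc> APC = 95.2% over 14 classes (7 empty classes excluded)
ev$under_threshold
#> [1] 0.02857143
```

An average per-class accuracy (APC — macro-averaged recall) of 95.2% with
2.9% of images under the 0.7 confidence threshold. Per-node calibration
temperatures and NLL improvements sit in `trained$calibration`.

Classify a synthetic 20-sample fossil sequence and zone it:

```r
depths <- seq(10, 200, by = 10)
# `composition`: two assemblage regimes switching at 100 cm; the full
# construction is spelled out in scripts/acceptance.R
dg <- cmd_diagram(cfg, trained, composition, n_objects = 100)
dg$zonation
#> <zonation> 20 samples, total dispersion 2.5735
#>   selected k = 2 zones; boundaries at depth(s) 105
```

The broken-stick rule recovers the two planted assemblage zones with the
boundary at 105 cm — the midpoint between the last upper-regime sample
(100 cm) and the first lower-regime one (110 cm). Recovered per-class
abundance trajectories correlate with the generating truth at r ≥ 0.97
for every class above 5% mean abundance. `percentages()`,
`concentration()`, `influx()` and `diagram_table()` turn the same counts
into diagram-ready tables, and `plot_diagram()` draws a reference
percentage diagram.

A thin command-line wrapper over the same functions is installed at
`inst/cli/palynet.R` (`generate | train | classify | evaluate | zonate`).

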