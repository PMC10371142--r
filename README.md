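# oximescreen

In silico discovery of broad-spectrum antidotes for organophosphate (OP)
poisoning within the substituted phenoxyalkyl pyridinium oxime (SPPO)
chemotype.

OP anticholinesterases (nerve agents, some insecticides) inhibit
acetylcholinesterase (AChE); oxime antidotes reactivate the enzyme but most
carry a permanently charged pyridinium and stay out of the brain. SPPOs — a
pyridinium aldoxime joined by an *n*-carbon alkyl linker to a substituted
phenoxy ring (positions R1–R5) — are a chemotype aimed at brain-penetrant
reactivation. `oximescreen` is for medicinal/computational chemists
prioritizing which SPPOs to synthesize next. It provides:

- **R-group decomposition**: factor assayed SPPOs into one of three shared
  scaffolds (oxime ortho/meta/para to the ring N⁺), the linker length *n*,
  and positioned substituent fragments, with `reassemble(decompose(m)) == m`
  on canonical SMILES;
- **rule-constrained enumeration** of a deduplicated virtual library:
  *n* ∈ {3, 4, 5}; R3 restricted to fragments observed at R3; R1/R2/R4/R5
  drawn from the pooled fragments observed at those positions;
- an **AChE reactivation classifier** — extreme gradient boosting on paired
  SPPO:OP descriptor vectors (the toolkit's full 2D battery, prefixed
  `sppo__`/`op__`) — predicting *No* (≈0%), *Low* (≤40%) or *High* (>40%)
  percent reactivation, with k-means-stratified 80/20 splitting, min-max
  scaling fit on training rows, variance filtering, grid-searched
  hyperparameters and importance-ranked reduced-set (RS) selection by
  cross-validated macro F1. *Broad spectrum* = predicted High against all
  five panel OPs (PIMP, NEMP, paraoxon, DFP, GV);
- a **BBB permeability classifier** built identically on single-molecule
  descriptors, classes from thresholding logBB at 0 (`BBB+` above);
- a **screening funnel**: enumerate → broad-spectrum → BBB → pluggable
  synthesizability backend (external retrosynthesis adapter, documented
  heuristic, or always-pass), with per-stage survivor counts and full
  provenance;
- **synthetic fixtures** that emulate the assay table (596 SPPO:OP pairs,
  260/226/110 class mix, 19-fragment R3 pool) and the logBB regression set
  (1058 molecules), so everything runs and tests offline.

Low-level cheminformatics (SMILES canonicalization, descriptors, SMARTS,
molecule graphs) is delegated to RDKit via a batched Python helper shipped
in `inst/python/`; every other step is R.

## Worked example

```r
library(oximescreen)

# emulated assay inputs: 30 SPPOs x 4 OPs, labels planted by a known rule
fx <- generate_sppo_fixture(n_sppos = 30, seed = 7)

# decompose, pool fragments, derive the generation rules
decs  <- decompose(fx$sppos)
pool  <- fragment_pool(decs)
rules <- enumeration_rules(r3_whitelist = "*OC", swap_pool = c("*C", "*Cl"),
                           n_values = 3:5, scaffolds = "pyr4")
lib   <- enumerate_candidates(rules, exclude = fx$sppos$smiles)
lib
#> <candidate_library> 135 candidates (243 combinations, 108 duplicates removed, 0 inputs excluded)

# train and evaluate the reactivation model
model <- train_reactivation_model(fx$measurements, fx$sppos, fx$ops, seed = 7)
model$tally
#>  No Low High
#>  52  46  22
round(model$evaluation$overall_accuracy, 3)
#> [1] 0.913
head(model$subset$names, 3)
#> [1] "sppo__MolLogP" "sppo__TPSA"    "sppo__SPS"

# per-OP predictions and the broad-spectrum flag for new candidates
hits <- predict_broad_spectrum(model$artifact, fx$sppos[1:5, ],
                               ops = op_panel(), scaler = model$scaler,
                               chem_columns = model$chem_columns)
```

The tally is the class composition of the assembled pair dataset; accuracy
is on the k-means-stratified 20% hold-out; `model$subset$names` is the
optimal reduced descriptor set — on fixtures it recovers the planted rule's
descriptors (SPPO TPSA and logP). `run_pipeline(pipeline_config(...))`
chains the whole funnel and writes `survivors.smi.gz`,
`screening_records.jsonl`, `summary.json` and the model artifacts. A thin
CLI wrapper lives at `inst/cli/oxime-screen.R`
(`make-fixtures` / `enumerate` / `run`).

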