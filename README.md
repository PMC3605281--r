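# lognet — training logic models of protein signaling networks

Signaling networks are known mostly as *possible* interactions: pathway
databases record that EGF can activate SOS-1, that IκB can sequester NF-κB,
and so on, without saying which interactions are functional in a particular
cell type. `lognet` turns such a prior knowledge network (PKN) into a
context-specific model by training it against perturbation data: cells are
treated with combinations of stimuli and kinase inhibitors, a panel of
phosphoproteins is measured, and the package searches for the sub-network
that best explains those measurements.

The PKN (a SIF file) is compressed — unmeasured, unperturbed pass-through
species are spliced out — and expanded into a *scaffold* of candidate logic
gates: for a node with inputs B and C, the gates `B→A`, `C→A` and
`B∧C→A` are created, with `B∨C` expressed by co-selecting the two single
gates. A candidate model is a bitstring *P* over the scaffold's *r* gates,
scored by the bipartite objective

θ(P) = θ_f(P) + α·θ_s(P),  with
θ_f = (1/n_g) Σ_k Σ_l Σ_t (B^M_{k,l,t} − B^E_{k,l,t})²  and
θ_s = (1/v_es) Σ_e v_e P_e,

the mean squared deviation between model prediction and normalized data over
all matched condition/readout/time cells, plus a size penalty counting
selected gate inputs, weighted by the tunable α. A seeded genetic algorithm
minimizes θ, archives every model it evaluates, and reports the *family* of
models within a user tolerance of the optimum together with per-gate
selection frequencies.

Five logic formalisms share this pipeline, trading simplicity against the
dynamic features they can represent:

| formalism | function | captures |
|---|---|---|
| Boolean, 1 steady state | `ga_optimize()` + `boolean_objective()` | pathway activation at one pseudo-steady time |
| Boolean, 2 steady states | `train_two_steps()` | slow feedback (e.g. transient ERK) via gate locking |
| discrete time | `train_dt()` | transients and oscillations, one time-scale factor δ |
| constrained fuzzy logic | `train_fuzzy()` | partial activations via gain-capped normalized Hill transfers |
| logic-based ODEs | `fit_ode()` | full continuous dynamics (normalized HillCube, per-node τ) |

`run_pipeline()` drives any of them end-to-end from a SIF + MIDAS pair to a
directory of artifacts (normalized data, scaffold, search archive,
edge-frequency attribute files, DOT export, fit plots, score summary, and a
reproducibility manifest). A thin command-line front end is installed at
`inst/cli/lognet.R`.

## Worked example

The package ships a generator for its reference problem: a 10-node toy
network of the EGF and TNFα pathways with three planted behaviors
(transient ERK, damped NF-κB oscillation, partial p38 under
co-stimulation), and simulated MIDAS data.

```r
library(lognet)
write_sif(toy_pkn(), "toy_pkn.sif")
toy_data(toy_spec(seed = 1), path = "toy_data.csv")

net  <- read_sif("toy_pkn.sif")
data <- read_midas("toy_data.csv")
scaffold <- preprocess(net, data)
scaffold
#> Scaffold: 7 nodes, 11 candidate gates (total inputs v_es = 14)
#>   ras=ERK
#>   NFkB=IkB
#>   !IkB=NFkB
#>   ...

fit <- ga_optimize(scaffold$n_gates,
                   boolean_objective(scaffold, data, time_index = 5,
                                     cfg = scoring_config(alpha = 0.005)),
                   ga_config(pop_size = 30, generations = 120,
                             mutation = 1.5, stall = 40, seed = 1))
fit
#> Search result: best score 0.0541159 (3 gates selected),
#> 612 models evaluated, family of 10

labels <- vapply(scaffold$gates, `[[`, "", "label")
data.frame(gate = labels, selected = fit$best_bits,
           frequency = round(fit$frequency, 2))
#>              gate selected frequency
#> 1         ras=ERK        1       1.0
#> 2        NFkB=IkB        0       0.4
#> 3       !IkB=NFkB        0       0.0
#> 4       TNFa=NFkB        1       0.8
#> 5  !IkB+TNFa=NFkB        0       0.6
#> 6        TNFa=p38        0       0.0
#> 7         ras=p38        0       0.0
#> 8    TNFa+ras=p38        0       0.0
#> 9        !ERK=ras        0       0.0
#> 10        EGF=ras        1       1.0
#> 11   EGF+!ERK=ras        0       0.5
```

Read: at the early pseudo-steady time (index 5, t = 8) the Boolean
steady-state fit selects the EGF→ras→ERK cascade and TNFα→NF-κB
(frequency 1.0 and 0.8 across the model family) but leaves the ERK
feedback gates unselected — a steady-state model cannot use a negative
feedback, which under synchronous updating only oscillates. Training the
same scaffold with `train_two_steps()` (early + late time) adds exactly the
`EGF+!ERK=ras` feedback at the second time scale, `train_dt()` picks up the
NF-κB/IκB loop that generates the oscillation, `train_fuzzy()` fits the
half-maximal p38, and `fit_ode()` reproduces all three behaviors; the
vignette (`vignettes/logic-modeling.Rmd`) walks through the methods and the
design choices behind them.

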