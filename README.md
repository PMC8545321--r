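# carpath

Atom-conserving pathway search in metabolic networks, for metabolic
engineers and systems biologists who need to extract biologically
meaningful linear pathways from large reaction databases — including
hypothetical networks from retrobiosynthesis tools — without hand-curating
cofactor blacklists.

## The idea

Every atom-mapped reaction is decomposed into reactant–product pairs, and
each pair is weighted by its **Conserved Atom Ratio**: with `n_c` shared
non-hydrogen atoms out of `n_r` reactant and `n_p` product heavy atoms,

    CAR_r = n_c / n_r,   CAR_p = n_c / n_p
    CAR   = (CAR_r + CAR_p) / 2 * (1 - |CAR_r - CAR_p|)

so a pair scores 1 only when the two molecules share their full heavy-atom
set, and a small fragment leaving a large molecule scores low. Coenzyme A
moieties shared by both sides of a pair are contracted to a single
pseudo-atom so the acyl chemistry dominates. The CAR becomes a graph
distance (`1/CAR`, `sqrt(1/CAR)` or `exp(1/CAR)/e`), stereoisomers are
merged on InChIKey connectivity blocks, and Yen's k-shortest loop-less
path search ranks pathways by summed distance — shortcuts through hub
metabolites (CO2, ATP, H2O) score badly because their pairs conserve few
atoms. The CAR doubles as a classifier of "main" biotransformation pairs;
an ROC/Youden analysis selects the 0.34 cutoff used for the unweighted,
thresholded network view and its diagnostics (components, diameter,
connectivity warnings).

## Worked example

The bundled hub-shortcut fixture contains a 2-step route through a lossy
hub (CAR 0.2 per step) and a 5-step chain of well-conserving steps
(CAR 0.9). Under the exponential transform the chain wins:

```r
library(carpath)
fx <- makeHubShortcut()
g  <- buildPairGraph(fx$pairs, fx$compounds, transform = "exp")
ps <- yenKShortest(g, "C10000", "C10007", k = 3)
ps
#> PathwaySet: 2 pathway(s) C10000 -> C10007 (transform = exp, k = 3)
#>  index pathway_length                                  intermediates
#>      1              5 C10000->C10003->C10004->C10005->C10006->C10007
#>      2              2                         C10000->C10001->C10007
#>                            reaction_ids pathway_score average_car
#>  R90003->R90004->R90005->R90006->R90007          5.59        0.90
#>                          R90001->R90002        109.20        0.20
```

The five conserving steps cost 5.59 in summed distance while the two-step
shortcut costs 109.20, so the biologically meaningful chain ranks first;
its average CAR of 0.90 says each step keeps ~90% of the atoms moving.
Network diagnostics on the same graph show what the 0.34 CAR threshold
does to connectivity — the hub drops out:

```r
analyzeNetwork(g, carThreshold = 0.34)
#> NetworkReport
#>   weighted graph: 7 nodes, 7 edges (14 directed arcs)
#>   unweighted view (CAR > 0.34): 7 nodes, 5 edges
#>   components: 2; biggest: 6 nodes (85.7%), 5 edges (100.0%)
#>   diameter of biggest component: 5
```

And the classifier view of the CAR, on a labelled pair population whose
separation emulates the curated reference set:

```r
rocAnalysis(makeLabeledPairs(seed = 1))
#> RocTable: 100 cutoffs, 5148 positives / 5599 negatives
#>   AUC = 0.8783; Youden max = 0.6089 at cutoff 0.33
```

An AUC of 0.88 means the CAR separates main from ancillary pairs well;
the Youden-optimal cutoff lands at 0.33 on this draw, next to the 0.34
default used throughout.

A command-line wrapper ships in `inst/exec/carpath` with subcommands
`pairs`, `search`, `stats`, `roc` and `fixtures`; see
`vignettes/car-weighted-pathway-search.Rmd` for the model, parameter and
design documentation.

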