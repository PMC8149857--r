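# qsperceptron

Simulation and training of a **bacterial perceptron** built from
quorum-sensing *Escherichia coli* consortia.

Engineered *sender* strains convert a chemical input bit — the
acyl-homoserine lactone OC6 — into production of a second signalling
molecule (OHC14), reported by mCherry. The strength of each sender's P_lux
promoter acts as a perceptron weight *w_i*; a P_lux *repressor* promoter
implements a negative weight. *Receiver* strains pool the OHC14 produced by
all senders — a weighted sum **w**·**x** of the input pattern **x** — and
convert it into EYFP through a sharp positive-feedback activation function
σ, so the consortium computes

    R(x) = σ( Σ_i w_i x_i ),

a single-layer perceptron in living cells. Both cell types are described by
Hill transfer functions. Activator promoters follow

    f(x) = β_m (x/K_d)^n / (1 + (x/K_d)^n) + β_m β_0

and the repressor promoter follows

    f(x) = α_m / (1 + (x/K_d)^n) + α_0 α_m ,

whose amplitude enters the network as the signed weight `α̂_m = −α_m`. The
package provides:

* **Transfer functions** (`hillActivator`, `evalActivator`,
  `evalRepressor`) and a registry of the eight characterized circuits
  (`defaultRegistry()`): receiver positive-feedback and open-loop
  topologies, four mutated P_lux senders, the P_lux repressor, and the
  receiver activation function on the sender-mCherry axis.
* **Least-squares fitting** of dose–response tables on the log scale
  (`fitActivator`, `fitRepressor`), with convergence, degeneracy and
  poor-fit diagnostics and noiseless/noisy round-trip guarantees.
* **Pattern sets** (`makePatternSet`, `makeNonbinary`, `enumerate4bit`):
  category-labelled N×N grids (one clean pattern plus N² single-bit-flip
  noisy variants per category, giving (1+N²)×3 patterns), graded variants
  sharing one per-size random scaling vector, and the sixteen 4-bit
  patterns.
* **The forward consortium model** (`consortiumNetwork`, `weightedSum`,
  `forwardResponse`, `responseMatrix`, `countUniqueProducts`).
* **Weight learning** (`trainWeights`, `trainMulticlass`): gradient descent
  through the receiver activation function with a halve-on-overshoot
  learning rate, followed by projection onto a discrete palette of
  realizable promoter strengths and direct-search refinement
  (`projectDiscrete`, `directSearch`, `coordinateSearch`).
* **Workflow surface**: `runPipeline()`, `makeFixtures()`, `cmdFit()`, and
  a command-line wrapper in `inst/cli/qsperceptron.R` with subcommands
  `fit`, `patterns`, `train`, `simulate`, `evaluate`, `pipeline`,
  `fixtures`.

## Worked example

```r
library(qsperceptron)

## the receiver activation function at its half-maximal point
receiverResponse(registryRow("R_mCh"), 1103)
#> [1] 11221.2

## 4-bit classification with the calibrated weight vector
net <- consortiumNetwork(c(450, 3500, 900, 3500))
weightedSum(net, c(1, 0, 1, 1))
#> [1] 4850
sel <- selectSeparable(enumerate4bit(), c(450, 3500, 900, 3500), 4000, 4500)
sort(sel$products)
#>  [1]    0  450  900 1350 3500 3500 3950 3950 4400 4400 4850 4850 7000 7450
#> [15] 7900 8350

## train one weight vector per category on the 3x3 pattern set
ps  <- makePatternSet(3)          # 30 patterns: (1 + 9) x 3 categories
res <- trainMulticlass(ps, trainingConfig(seed = 1, directSearchRadius = 4))
res$margins
#>        z        v        n
#> 11728.41 14244.88 14244.88
```

`weightedSum` is the collective OHC14 proxy on the mCherry axis (4850 for
pattern `[1,0,1,1]`, above the upper decision threshold 4500, so the
pattern classifies into the high set). The margins are the smallest
own-category EYFP response minus the largest foreign response — positive
margins mean every noisy variant of a category outscores every pattern of
the other categories.

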