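# muklock

Analysis toolkit for chromosome entrapment studies of the bacterial SMC
complex **MukBEF**. MukBEF is a ring-shaped ATPase that organises the
chromosome into loops and is unloaded at *matS* sites in the replication
terminus (*Ter*) macrodomain by the *matS*-binding protein MatP. Probing how
DNA threads through the complex — the "double lock", in which the two arms
of one DNA loop are separately entrapped in the kleisin-delimited *ring* and
*clamp* compartments — requires a chain of bespoke computations around the
wet-lab experiments. This package implements that chain as reusable, tested
R functions for molecular microbiologists and structural biologists:

- **matS discovery** (`scanMotifs`, `cumulativeGCSkew`, `rankSiteFamilies`):
  degenerate (`N`-wildcard) and edit-distance (Levenshtein, d ≤ 2) motif
  scanning of circular genomes, replication ori/ter prediction from the
  cumulative GC skew S(i) = Σ (n_G − n_C)/(n_G + n_C), and ranking of motif
  families by median circular distance to the terminus.
- **Gel densitometry** (`movingMedianBackground`, `quantifyBands`,
  `posteriorMuCI`, `relativeSignalCI`): moving-median background
  subtraction, band fractions, and Bayesian credible intervals under a
  normal likelihood with priors μ ~ U[0,1] (or U[−10x̄, 10x̄] for relative
  signals) and p(σ) ∝ 1/σ².
- **Cross-linking combinatorics** (`enumerateSpecies`,
  `findCovalentCircles`, `inferSiteEfficiency`): expected covalent species
  fractions from independent per-site efficiencies p_i
  (P(S) = Π_{i∈S} p_i Π_{j∉S} (1 − p_j)), detection of covalent protein
  circles (ring / clamp / frame), and inversion of observed precursor
  depletions to implied site efficiencies.
- **Entrapment topology** (`isCatenated`, `predictRetention`,
  `consistentConfigs`): catenation-parity model of the agarose-plug
  entrapment assay — a compartment retains DNA iff some closed DNA crosses
  it an odd number of times; frame crossings = ring + clamp crossings.
- **EMSA binding fits** (`equilibriumBoundFraction`,
  `simulateRateEquation`, `fitTitration`): depletion-aware equilibrium
  bound fraction (the root of PD² − (P_t + D_t + K_d)·PD + P_t·D_t = 0 in
  [0, min(P_t, D_t)]), a rate-equation relaxation in an arbitrary time
  domain, and
  the fit parametrised by (k_d, baseline, asymptote) with k_a an arbitrary
  constant and K_d = k_d/k_a.
- **Structural geometry** (`readStructure`, `fitDuplexAxis`,
  `crossingAngle`, `minBackboneVdwDistance`): PDB/mmCIF input, DNA helix
  axes from base-pair midpoints, inter-duplex crossing angles
  (Θ = arccos|a·b|), and minimum backbone van der Waals distances
  min(‖x_i − x_j‖ − r_i − r_j).
- **Synthetic data** (`genGenome`, `genLaneProfile`, `genTitration`,
  `genHelixScene`, `genReplicates`): seeded generators with recorded ground
  truth for every input class, so the whole pipeline is testable offline.

A thin command-line front end (`muklockCLI()`, wrapper in
`inst/scripts/muklock`) exposes the pipeline as subcommands
(`simulate`, `scan-mats`, `skew`, `rank`, `quantify-gel`, `xlink-species`,
`xlink-infer`, `entrapment`, `fit-emsa`, `struct-angle`, `struct-vdw`,
`identity`). All file outputs use 0-based, half-open coordinates.

## Worked example

```r
library(muklock)

## a 50 kb circular genome with opposite-skew replichores and one planted matS
tr <- genGenome(50000, skewAmplitude = 0.3, seed = 7,
                planted = list(list(pattern = "GTTACATTGTAAC",
                                    pos = 24000, n_mut = 0)))
cumulativeGCSkew(tr$genome, window = 1000)
#> SkewProfile: 50 windows of 1000 bp (step 1000) over 50000 bp
#>   ori = 0, ter = 25000 (0-based)

scanMotifs(tr$genome, "GTTACNNNGTAAC")
#> GRanges object with 1 range and 3 metadata columns:
#>               seqnames      ranges strand | edit_distance   matched_seq ...
#>   [1] synthetic_genome 24001-24013      + |             0 GTTACATTGTAAC
```

The terminus is called exactly at the planted position (25000 = ori +
length/2) and the planted site is the unique degenerate-pattern hit; its
family ranks first by median terminus distance (993.5 bp on this genome).

```r
inferSiteEfficiency(0.29, 0.12)
#> [1] 0.5862069
```

A head-cysteine species that drops from 29% to 12% of molecules once hinge
cysteines are present implies a hinge cross-linking efficiency of 58.6%
(a reduction by roughly 60%) — in agreement with the 62% measured for the
hinge alone.

```r
consistentConfigs(c(ring = TRUE, clamp = TRUE, frame = FALSE),
                  mukbefCandidateConfigs())
#> $double_lock  (the only consistent threading topology)
```

Of the seven shipped threading topologies, only the double lock predicts
retention in ring and clamp but not in the frame.

```r
tt <- genTitration(50, 0.05, 0.95, proteinConcs = c(0, 2^(0:10)),
                   dnaTotal = 2, noiseSd = 0.01, seed = 3)
fitTitration(tt$series)
#> BindingFit: K_d = 54.61 nM (k_d = 54.61, k_a = 1)
#>   baseline 0.05823, asymptote 0.9603, rss 0.0008512

posteriorMuCI(c(0.60, 0.63, 0.62))
#> 95% credible interval: [0.5937, 0.6396]
#>   posterior mean 0.6167 (posterior sd 0.0121, replicate sd 0.0153)
```

A 12-point titration of 2 nM DNA generated at K_d = 50 nM with 1% noise is
recovered within 10%; triplicate efficiencies get an equal-tailed 95%
credible interval.

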