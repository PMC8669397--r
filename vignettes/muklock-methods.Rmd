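---
title: "Models and methods behind muklock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind muklock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muklock)
```

muklock collects the computations needed to analyse how the SMC complex
MukBEF entraps chromosomal DNA: candidate *matS* site discovery, gel
quantification with credible intervals, cross-linking species modelling,
catenation-parity inference, equilibrium binding fits, and structural
geometry. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical and design choices; it also describes what
the synthetic generators do and do not emulate.

## matS discovery on circular genomes

*matS* is a degenerate 13-bp palindrome. Two scan modes cover the two ways
"similar to the consensus" is operationalised:

- **Degenerate mode** (`maxEdit = 0`, `N` wildcards): a window matches if
  every non-`N` position is identical. This is how the abundant candidate
  family `GTTACNNNGTAAC` is counted.
- **Edit mode** (`maxEdit = k`): a locus is reported when some anchored
  window of length $|p| - k \dots |p| + k$ is within $k$ Levenshtein edits
  of the pattern; the minimum distance is reported. A banded
  dynamic-programming kernel (band width $2k+1$) keeps a 5 Mb genome scan
  at $d \le 2$ in the seconds range. Whether "edit distance" should permit
  indels inside a 13-mer is genuinely ambiguous; Levenshtein is the
  default and `method = "hamming"` provides the substitution-only reading.

Circular genomes are scanned across the origin by extending the text with
the first $|p| + k - 1$ bases. Overlapping hits of one pattern (starts
closer than the pattern length, including the wrap pair) collapse to the
minimum-distance, smallest-start representative, so one biological site is
one hit. A palindromic pattern (with `N` treated as self-complementary)
matches both strands at the same locus and is reported once on the forward
strand; non-palindromic patterns are also scanned as their reverse
complement and reported with strand. Hits are returned as a `GRanges`
(1-based internally, as usual in R); all TSV outputs are 0-based,
half-open.

### Terminus prediction from cumulative GC skew

Per window, skew $= (n_G - n_C)/(n_G + n_C)$ (0 for G+C-free windows);
the cumulative curve is its running sum. On circular bacterial chromosomes
the leading strand is G-biased, so the cumulative curve rises from the
origin to the terminus: the **terminus is called at the global maximum**
and the origin at the global minimum. Calls are reported at the *end
boundary* of the extremal window: for the cumulative sum, the value after
$i$ windows belongs to the boundary coordinate, which makes the
single-base-window case exact (on `GGGGGCCCCC` the maximum after 5 bases
is boundary 5 and the minimum after 10 bases is boundary 10 ≡ 0, the
origin). Ties break to the smallest genomic coordinate, and a flat profile
yields `NA` calls. Defaults are 1000 bp non-overlapping windows —
boundary-call resolution is then ±window, well below the 5% of genome
length the downstream ranking needs. The sign convention (ter = maximum)
is stated explicitly because published skew analyses differ in it.

Families are ranked by the *median* circular distance from hit midpoints
to the called terminus (`rankSiteFamilies`), ascending, with lexicographic
tie-breaks. Midpoints (not starts) are used; for 13-mers the difference is
immaterial but midpoints are rotation-symmetric.

### Global identity

`globalIdentity` is Needleman–Wunsch global alignment with match +1,
mismatch 0 and linear gap −1 (via Biostrings' aligner), reporting
$100 \times$ matches / alignment columns, gap columns included in the
denominator. The denominator choice is stated because percent-identity
figures are only interpretable relative to it.

## Gel densitometry and credible intervals

The background of a lane profile is the **running median** over a centred
window with reflected edges; medians ignore sharp bands riding on smooth
drift. Even window sizes round up to odd with a notice. The default window
is 3× the widest declared band window — wide enough that a band occupies
under half the window and cannot drag the median. Band areas are
trapezoidal integrals of the background-subtracted signal clamped at zero,
normalised to fractions. Two useful invariances follow directly: adding a
constant to the lane shifts the background by the same constant, and
rescaling the lane leaves fractions unchanged.

Replicate efficiencies get a posterior under a normal likelihood with
unknown $\sigma$:
$$p(\mu, \sigma \mid x) \propto \sigma^{-n}
  e^{-\sum_i (x_i - \mu)^2 / 2\sigma^2} \cdot \sigma^{-2},$$
with $\mu \sim U[0, 1]$ (the efficiency scale) and the $1/\sigma^2$ prior
truncated to $[10^{-4}, 10] \times \mathrm{range}(x)$ for propriety.
$\sigma$ is marginalised numerically on a log-spaced grid (default) or in
the closed form $S(\mu)^{-(n+1)/2}$ with
$S(\mu) = \sum_i (x_i - \mu)^2$; the two agree to $10^{-3}$ in interval
endpoints and the tests assert it against an independent brute-force 2-D
grid. Intervals are **equal-tailed** (not HPD): for symmetric posteriors
they coincide, and equal-tailed quantiles are directly verifiable against
the gridded CDF. Both the posterior sd and the plain replicate sd are
reported, since "±" summaries in the literature may denote either.

For entrapment assays the data are per-replicate ratios
$x_i / \bar{x}_{\mathrm{ref}}$ and the mean prior is
$U[-10\bar{x}, +10\bar{x}]$ — data-dependent bounds, the only reading of a
"$\pm 10\mu$" prior that gives a proper finite interval; it deliberately
admits negative means so that zero-signal samples produce intervals
straddling 0. When the ratios are identically zero this prior collapses,
so a fixed half-width of 1 and an absolute $\sigma$ floor ($10^{-6}$) are
substituted for that degenerate case only.

## Cross-linking species and covalent circles

The species model assumes **independent site reactions**: the probability
of outcome $S$ (the set of reacted sites) is
$\prod_{i \in S} p_i \prod_{j \notin S} (1 - p_j)$. Independence is a
model assumption, implied by the "expected ratios" arithmetic it
reproduces, not an established fact; deviations (e.g. conformational
coupling between sites) would show up as depletions inconsistent with
`inferSiteEfficiency`, which inverts an observed depletion
$f_{\mathrm{alone}} \to f_{\mathrm{combined}}$ to the implied second-site
efficiency $1 - f_{\mathrm{combined}}/f_{\mathrm{alone}}$.

Covalent connectivity is a multigraph on chains with reacted sites as
edges. `findCovalentCircles` reports every elementary cycle (connected
edge subset with all vertex degrees 2; a same-chain link is a one-edge
cycle) and names cycles by matching site sets against the template's
compartment table. The shipped MukBEF template has chains
$\kappa$-MukB / $\nu$-MukB (the reporter type) and MukF, sites hinge and
head (B–B) and cap and neck (F–B), and compartments ring = {cap, neck,
hinge}, clamp = {cap, neck, head}, frame = {head, hinge}; with all four
sites reacted the cycle space contains all three named circles. MukE is
omitted because no MukE cysteines are used. Gel species identity is keyed
on the covalent component containing the reporter chains, matching
fluorescence detection. Exhaustive enumeration is capped at 20 sites
($2^{20}$ outcomes); the templates of interest have 4.

## Catenation parity and the entrapment assay

Retention in the denaturing plug assay is modelled purely by **crossing
parity**: a closed DNA is catenated with a covalent protein circle iff it
crosses a spanning disk an odd number of times. No embedding geometry,
linking-number sign, or supercoiling energetics is tracked — parity
suffices to reproduce every qualitative retention claim the assay makes.
The frame compartment is the union circle, so its crossings are the
per-component sum of ring and clamp crossings (derived, never stored);
for a single DNA component this forces frame = ring XOR clamp, which is
why ring-only retention without frame retention is impossible for one
component, and why the observed pattern (ring and clamp retained, frame
not) singles out the double lock.

The shipped candidate set encodes: double_lock (1,1); ring_only (1,0);
clamp_only (0,1); sisters as two components (1,0)+(0,1);
parallel_axis_loop as a single component (1,0) with a note — its precise
threading is only known schematically, and the encoding records the one
property that matters here, that the enclosed loop tip catenates the
frame; pseudo_topological (2,0); non_topological (0,0).

## Equilibrium binding fits for EMSA

At 2 nM labelled DNA, free-protein depletion is not negligible against
nanomolar $K_d$ candidates, so the equilibrium bound fraction solves the
quadratic $PD^2 - (P_t + D_t + K_d)PD + P_t D_t = 0$ exactly (smaller
root, evaluated in the cancellation-free form $2 P_t D_t / (b +
\sqrt{b^2 - 4 P_t D_t})$); the no-depletion hyperbola is available as an
option. `simulateRateEquation` integrates
$d[PD]/dt = k_a (P_t - PD)(D_t - PD) - k_d\,PD$ in an arbitrary time
domain (deSolve, `lsoda`, rtol $10^{-10}$) with default
$t_{\mathrm{end}} = 100/k_d$, checks convergence at $t_{\mathrm{end}}$,
and must agree with the algebraic equilibrium to $10^{-6}$ — the tests
assert this cross-operation identity on random parameter triples.

`fitTitration` follows the rate-equation parametrisation: free parameters
$(\log k_d, \mathrm{baseline}, \mathrm{asymptote})$ with $k_a$ an
arbitrary fixed constant and $K_d = k_d/k_a$, which is invariant under
rescaling $k_a$ (asserted over six decades). Optimisation is Nelder–Mead
with multi-starts at $K_d$ values spanning every decade of the titrated
concentration range (plus one decade either side), each polished by a
second restart; the best residual sum of squares wins. Identifiability
guards: at least 5 points, a ≥10-fold concentration range, non-flat
response. Protein concentration means the MatP dimer, with 1:1
dimer-to-site stoichiometry — a single binding equilibrium, no
cooperativity or multi-site competition.

## Structural geometry

`readStructure` loads the first model from PDB or mmCIF via bio3d,
resolving alternate locations to the highest occupancy (then altloc 'A'),
and deriving elements from atom names where the element column is absent.

A duplex axis is the total-least-squares line (first principal component)
through **base-pair midpoints** of paired C1′ atoms (P fallback), pairing
the two strand selections antiparallel by index; at least 4 pairs are
required, and the RMS perpendicular deviation of midpoints from the line
is reported as a fit diagnostic. A midpoint line fit was chosen over
cylinder fitting because it is simpler and exact on ideal helices. The
crossing angle is $\arccos |a \cdot b| \in [0^\circ, 90^\circ]$ (acute
convention, symmetric and flip-invariant); a signed mode (sign from the
triple product with the inter-axis connector) exists but is flagged
experimental because sign conventions for plectoneme crossing angles are
not uniquely fixed by the geometry alone.

Minimum backbone van der Waals distances use protein backbone
{N, CA, C, O} (nucleic backbone {P, OP1, OP2, O5′, C5′, C4′, C3′, O3′}
for nucleotide residues) and a Bondi-type radii table (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80, H 1.20 Å), shipped explicitly and swappable
because interface measurements rarely state their radii source. The
minimum of $\lVert x_i - x_j \rVert - r_i - r_j$ over cross pairs may be
negative (interpenetrating surfaces); the attaining atom pair is attached
to the result. The implementation chunks the distance matrix for memory
but is exactly the all-pairs minimum — tests assert equality with a
brute-force double loop.

## Synthetic data: what it emulates, and what it does not

Every generator records its ground truth and derives its RNG stream from
(seed, purpose tag), so calls are independent, bit-reproducible, and leave
the caller's RNG state untouched.

- `genGenome` draws bases per replichore with
  $P(G) - P(C) = \pm a \,(P(G) + P(C))$, sign flipping at ori and ter
  (ter diametrically opposite ori), A and T sharing the non-GC mass
  uniformly at default G+C = 0.5 — skew is controlled independently of GC
  content. Planted motifs overwrite the background with exactly `n_mut`
  random substitutions (substitutions only, so recorded positions stay
  exact). It emulates replichore-scale skew and terminus-proximal site
  placement; it does not emulate codon structure, repeats, horizontally
  acquired islands, or local skew excursions, so scan specificity on real
  genomes (where near-misses are non-random) is not established by these
  tests.
- `genLaneProfile` composes a polynomial background (in the scaled
  coordinate $x/L$ for conditioning), area-normalised Gaussian bands —
  the standard densitometry peak shape, adopted because no particular
  band shape is canonical — and i.i.d. Gaussian noise. Real lanes add
  band asymmetry, smile, and speckle, which the moving median tolerates
  but these tests do not probe.
- `genTitration` maps the depletion-aware equilibrium curve affinely to
  [baseline, asymptote] and adds Gaussian noise; it shares
  `equilibriumBoundFraction` with the fit (deliberately: the fit's
  *statistical* recovery is the question; the *algebra* is verified
  separately against the independent ODE route).
- `genHelixScene` builds two ideal duplexes (rise 3.4 Å/bp, twist 36°/bp,
  anchor atoms on a 9.4 Å cylinder) rotated ±angle/2 about a common axis,
  so the true axes subtend the requested angle exactly; paired anchors
  are placed diametrically across the cylinder, putting base-pair
  midpoints exactly on the axis. Real DNA in complexes bends and breathes;
  the RMS axial deviation diagnostic, not these scenes, is what flags
  that.
- `genReplicates` draws i.i.d. normal values — matching the likelihood
  the posterior assumes, so posterior calibration on heavy-tailed real
  replicates is untested.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 20–50 kb genomes, 1000-point
lanes, 12-point titrations, 14–20 bp duplex scenes, and ≲160-atom VDW
selections; these sizes make every property cheap to verify exhaustively
while leaving each estimator comfortably in its asymptotic regime (e.g.
terminus calls to ±2% of genome length, $K_d$ to <10% at 1% noise).
`scripts/acceptance.R --seed S --out F` recomputes all headline quantities
deterministically from a single seed.

## Known limitations

- No PWM/probabilistic motif models; motif similarity is purely
  edit-distance based.
- Ori/ter prediction is the cumulative-skew extremum only.
- Lane profiles are 1-D; extracting them from 2-D gel images is out of
  scope.
- No cross-link reaction kinetics; efficiencies are endpoint
  probabilities.
- No knot/link invariants beyond crossing parity.
- Binding fits assume a single equilibrium (no Hill coefficients, no
  competing sites) and report no uncertainty on $K_d$ beyond the residual
  sum of squares.
- Accession-based reproduction of published structural and genomic
  measurements requires network access to NCBI/RCSB.
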