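---
title: "Scoring, profiling and mapping an inner-membrane complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, profiling and mapping an inner-membrane complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micoskit)
```

Characterising a membrane-embedded protein complex such as MICOS — the
~700 kDa mitochondrial contact site and cristae organizing system sitting at
cristae junctions (CJs) — typically combines three quantitative measurement
types: affinity purification-mass spectrometry (AP-MS) to map who binds
whom; SILAC blue-native PAGE (BN-PAGE) complexome profiling to watch the
complex assemble or fall apart when a subunit is removed; and immunogold
electron microscopy to place subunits relative to CJs. This vignette
explains the models behind each analysis, the parameters that matter, what
the synthetic-data generators emulate, and the design choices made where the
methodology left room.

## 1. AP-MS scoring against a background stats table

### Data model

The unit of input is a peptide-spectrum match (PSM) table per bait and
technical replicate. `assemble_apsm()` converts PSMs to per-protein counts,
apportioning peptides whose sequence matches several proteins. Two policies
are offered because protein inference from shared peptides has no single
right answer:

* **proportional** (default) splits a shared peptide's count across its
  matched proteins in proportion to their unique-peptide evidence (equal
  split when none has any). This conserves total spectral counts, which is
  the property the downstream abundance statistics rely on.
* **parsimony** assigns the count wholly to the protein with the most
  unique evidence and drops proteins supported only by shared peptides —
  an Occam's-razor inference that suits presence/absence questions.

`merge_replicates()` averages counts over the replicates *acquired*, not the
replicates detecting: a prey seen in one of two runs at 6 spectra gets
APSM 3 and replicate count p = 1. Averaging (rather than summing) keeps
APSMs comparable between baits run in different numbers of replicates; the
reproducibility information lost by averaging is retained separately in p,
which the WD score uses as an exponent.

### The CompPASS-style statistics

A single pulldown cannot distinguish a genuine partner from a sticky
ribosomal protein. The stats table — a panel of k unrelated baits processed
identically — provides the background model. For prey column j (zeros
included over all k baits) with mean $\bar{x}_j$ and sample standard
deviation $\sigma_j$:

$$\mathrm{WD}_{ij} = \sqrt{X_{ij}\left(\frac{k}{f_j}\,\omega_j\right)^{p_{ij}}},
\qquad \omega_j = \max\!\left(1, \frac{\sigma_j}{\bar{x}_j}\right),
\qquad Z_{ij} = \frac{X_{ij}-\bar{x}_j}{\sigma_j}$$

The three ingredients are frequency (rare preys score higher through
$k/f_j$), abundance ($X_{ij}$), and reproducibility (the replicate count
$p_{ij}$ exponentiates the frequency/variability term, so a prey seen in
both replicates of one bait but nowhere else scores far above a one-off).
The variability weight $\omega_j$ rescues preys that appear in many baits
but at very uneven levels — behaviour typical of true partners of several
related baits. $Z$ is reported but not used for filtering by default: it
captures abundance deviation alone and is redundant with WD's ingredients.

WD has arbitrary units, so it is normalised: NWD = WD / q, where q is the
98th percentile of all positive WD scores. The percentile is configurable
(`normalization_percentile`) because the convention that "NWD = 1" marks
the top tail is exactly that — a convention; 98 is the default because with
it roughly 2% of scored pairs clear the line, a manageable candidate list
at typical panel sizes. Quantile type 7 (R's default interpolation) is
used; ties at the threshold are resolved strictly (NWD must *exceed* the
threshold to pass).

`filter_hcips()` adds two orthogonal filters: a membership list (for
mitochondrial work, MitoCarta — supplied by the user as a plain identifier
list, since identifier mapping is dataset-specific) and a minimum APSM
(inclusive; 2 is the conventional choice for panels where single-spectrum
identifications are not trusted).

### Network assembly

`build_network()` treats baits as first-class nodes: bait–bait pulls are
edges, and a pair observed in both directions collapses into one edge
flagged reciprocal — reciprocity being the strongest internal validation
AP-MS offers. Evidence for one pair from different cell lines merges into a
single edge carrying all records (`merge_cell_lines = FALSE` keeps them
separate, since published edge counts differ in this convention and both
are defensible). Prey–prey edges never arise by construction: two preys are
only connected if one of them was itself run as a bait. Self-pulls are
dropped. Exports go through igraph (GraphML) or a plain edge-list TSV.

## 2. SILAC BN-PAGE complexome profiling

### Model

Control cells grown in light (K0) medium and knockdown cells in heavy (K8)
medium are mixed 1:1; mitochondrial complexes are separated on a BN-PAGE
lane cut into 20 slices spanning >1 MDa to <60 kDa, and each slice is
quantified by LC-MS. Because the two populations are mixed before lysis,
every peptide's heavy:light (H:L) intensity ratio in every slice directly
reads out the knockdown's effect on that protein *at that assembly state*:
H:L < 1 means loss from that mass region, H:L > 1 means accumulation.

`calibrate_fractions()` places slice edges uniformly in log10 mass —
electrophoretic migration is approximately linear in log mass — so the
default slice width is (log10 1000 − log10 60)/20 ≈ 0.061 log10 units. A
700 kDa complex lands in slice 3 and a 500 kDa species in slice 5.

`protein_fraction_ratios()` aggregates peptides to protein-per-slice ratios
by the quotient of summed intensities (default), which weights peptides by
signal and is robust to low-intensity outliers; median-of-peptide-ratios is
available (`method = "median"`) since both conventions are in common use.
One-channel cells are capped at 100 (floored at 1/100 when logging) and
flagged: infinite ratios would otherwise dominate window means, and 100
corresponds to a >99% knockdown, beyond any biologically plausible value.

### Shift calls

`detect_shift()` compares mean log2 H:L in a window of ±1 slice around the
mature-complex mass (default 700 kDa) against a window around the
sub-complex mass (default 500 kDa). At the default calibration these
windows would share slice 4; shared slices are assigned to the mature
window and excluded from the sub-complex window, so the two means are
estimated from disjoint fractions — otherwise a single mixed-provenance
slice dilutes both signals. The call threshold δ = log2(1.5) asks for at
least a 1.5-fold change in either direction; the measurements that motivate
this analysis report direction, not effect size, so δ is exposed as a
parameter rather than treated as truth.

Calls are resolved in precedence order: `subcomplex_shift` (mature down
*and* sub-complex up — disassembly into an intermediate), then `degraded`
(total abundance down without sub-complex accumulation — the protein is
lost outright, as happens to subunits that cannot integrate and are turned
over), then `depleted` (mature window down only), else `no_change`. The
precedence matters: a protein depleted everywhere satisfies the `depleted`
pattern too, but `degraded` is the informative call. Windows with no
quantified value return `insufficient_data` rather than a guess.

`render_heatmap()` uses the field's colour convention: green below H:L = 1,
red above, centred at log2 = 0, grey for missing cells.

## 3. Immunogold spatial analysis

Gold particles, CJ positions and cristae membranes are annotated in the
micrograph plane; distances are straight-line 2D nm (the measurements are
projections — no 3D correction is attempted, and CJs are treated as points
because the distance of interest is "to the nearest CJ"). Histograms use
50 nm bins by default — the scale at which CJ enrichment is conventionally
summarised — with half-open bins and an open-ended last bin.

The enrichment test formalises "enriched at CJs" as a Monte-Carlo
hypothesis test. The null is uniform placement *by arc length along the
annotated cristae membranes*, not uniform in the plane: an immunogold label
on a membrane protein is constrained to membranes under any hypothesis, and
a complex-I subunit distributed along cristae is precisely this null. Each
of `n_draws` draws places the observed number of particles uniformly along
the polylines and recomputes the statistic (default: mean nearest-CJ
distance); the one-sided p-value is $(1 + \#\{T_{null} \le
T_{obs}\})/(1 + n_{draws})$, the add-one form that can never return 0 and
is exact under exchangeability.

## 4. What the generators emulate — and what they do not

All three generators are deterministic given a seed and return ground truth
alongside the data, so every detection claim in the test suite is checked
against known labels.

**AP-MS** (`simulate_apms()`): each background prey gets a per-replicate
detection probability drawn from Beta(1.2, 10) (mean ≈ 0.11 — most preys
are rare, a few are frequent flyers), and detected cells draw
1 + NegBin(μ − 1, size) spectral counts, defaults μ = 4, size = 2;
spectral counts are overdispersed and the negative binomial reflects that.
Planted interactions superimpose a Poisson count at `multiplier` × μ per
replicate with configurable reproducibility. Not emulated: correlated
contaminant structure across baits (sticky proteins appearing together),
carry-over between adjacent runs, and abundance-dependent detection. A
recall of 1.0 on planted rare/abundant/reproducible pairs therefore shows
the scoring implements its definition, not that real HCIP lists are
error-free.

**Complexome** (`simulate_complexome()`): every subunit's light channel
follows a Gaussian migration profile in log10 mass centred on the complex
mass, width 0.03 log10 units so the complex spans ~1–2 slices (discrete
banding, as on a real gel); the heavy channel equals light × per-slice
effect (mature-window depletion, sub-complex-window accumulation, global
degradation) × independent lognormal noise, CV 0.2 per channel, with 5
peptides per protein and lognormal peptide response factors (sdlog 0.5).
Not emulated: missing-value structure from detection limits, co-migrating
contaminant complexes, smearing between slices, incomplete label
incorporation. The ≥95% recall/specificity figures certify the caller
against its own generative model at realistic noise, not against MaxQuant
output.

**Immunogold** (`simulate_micrograph()`): the default geometry is four
800 nm cristae with a junction at each origin. `uniform` mode samples
arc-length-uniform positions; `cj_concentrated` picks a CJ and displaces
the particle along the membrane by a half-normal(σ = 30 nm) arc distance in
a random direction, reflecting at polyline ends (reflection preserves the
half-normal distance law when the CJ sits at a membrane end). Isotropic
jitter models localisation error of the antibody-gold linkage. Not
emulated: section thickness effects, membrane curvature in 3D, antibody
steric exclusion near tightly curved necks.

## 5. Numerical choices and degenerate inputs

* Scoring requires k ≥ 2 (with one bait the background is undefined) and at
  least one detection; all-zero prey columns contribute ω = 1 by convention
  and are never emitted as pairs. Z is defined as 0 where σ = 0.
* Stats tables enforce X > 0 ⇔ p ≥ 1 at construction, so impossible states
  cannot propagate. TSV round-trips preserve bait/prey ordering and cell
  line through `#%` metadata comment lines.
* Empty PSM input yields an empty run; zero replicate runs is an error.
* `mass_to_slice()` clamps out-of-range masses to the terminal slices and
  flags them; slice intervals are half-open from the upper mass edge, so a
  mass exactly on an interior edge belongs to the lower (smaller-mass)
  slice and 1000 kDa itself belongs to slice 1.
* Monte-Carlo p-values use the add-one estimator (minimum attainable
  p = 1/(n_draws + 1)); histogram bin membership at an edge goes to the
  upper bin.
* Problem sizes in the test suite — 200 random panels for the brute-force
  oracle comparison, 100 complexome simulations per scenario, 200
  enrichment replicates at 199 draws — were chosen so the full suite runs
  in about a minute while keeping Monte-Carlo standard errors well inside
  the asserted margins.

## 6. Known limitations

* The scoring normaliser is estimated from the scored panel itself; on very
  small panels (k ≲ 6) the 98th percentile is interpolated from few points
  and NWD thresholds should be treated cautiously — exactly why published
  analyses use stats tables of tens to hundreds of baits.
* When planted/true interactions make up more than the top-percentile mass
  of the WD distribution, the normaliser shifts into the true-interaction
  range and recall at NWD > 1 drops below 1 by construction; precision is
  unaffected. This is a property of percentile normalisation, not a bug.
* The shift caller assumes the sub-complex is resolvable from the mature
  complex at the given calibration (≥ 2 slices apart after window
  exclusion); complexes closer in mass need more slices or narrower
  windows.
* Identifier harmonisation (gene symbols vs accessions, orthologs) is out
  of scope; all modules treat identifiers as opaque strings.
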