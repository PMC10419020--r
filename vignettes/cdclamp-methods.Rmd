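---
title: "Methods: methylation trees, clamp detection and binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation trees, clamp detection and binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdclamp)
```

`cdclamp` analyses supramolecular assemblies of a lipophilic guest with one
or two methylated β-cyclodextrins. This vignette records the models and
procedures the package implements, the defaults it ships, and the design
choices that were genuinely open — together with why they were resolved the
way they were.

## Site topology

A β-CD has 7 glucose units, each with substitutable oxygens at positions 2,
3 and 6 (positions 2 and 3 on the wide secondary rim, position 6 on the
narrow primary rim). The package numbers the 21 sites contiguously: site
$s$ belongs to glucose unit $\lceil s/3 \rceil$ at position
$(2,3,6)[(s-1) \bmod 3 + 1]$; a second CD uses global ids 22–42. This is
the unique contiguous scheme under which the site pairs (19, 20) and
(10, 11) are each the position-2/position-3 pair of a single anhydroglucose
unit — the configuration clamp bookkeeping depends on. The mapping is
exposed as `site_to_glucose()` / `glucose_to_site()`; models whose files
follow a different numbering can say so in the sidecar, which is the single
source of truth for atom roles.

Topology is *supplied*, not perceived: automatic pyranose-ring perception
from bare Cartesian coordinates is notoriously brittle and is not this
package's contribution. Every XYZ model travels with a JSON sidecar naming
molecule membership (guest / CD1 / CD2), the oxygen and substituent atom of
each site, the ether and anomeric acceptor oxygens, and the guest's
functional atoms (Fe, phenol O–H pairs, imide carbonyls, moiety sets).
Atom indices are 1-based throughout, matching R convention. The
methylation state is read off the geometry by the substituent element:
carbon means methylated, hydrogen means hydroxyl.

## Hydrogen-bond and clamp detection

A contact is reported when a registered donor-H/acceptor class pair lies in
different molecules with H⋯acceptor distance ≤ cutoff. The default cutoff
is **2.0 Å**, appropriate for PM3-minimized geometries; DFT geometries put
the atypical Fe⋯H contacts near 2.7 Å, so the cutoff is a plain argument
(`detect_hbonds(model, cutoff = 2.8)`).

Detection is **distance-only by default**. The donor–H⋯acceptor angle is
always computed and reported, but not used as a filter: reference
geometries include accepted intra-CD contacts as bent as 108°, so imposing
a conventional 120°–150° gate would silently change the census. An
optional `angle_min` gate exists for users who want one.

The class registry is a plain tibble of (donor class, acceptor class)
pairs. The default enumerates seven intermolecular classes: CD hydroxyls
donating to Fe, to each of the two imide carbonyls, and to the phenol
oxygens; and phenol hydroxyls donating to CD hydroxyl, ether and anomeric
oxygens. Splitting the two imide carbonyls — rather than, say, adding a
phenol→Fe pair, which would be intramolecular on the guest and can never
fire — is what brings the count to seven while keeping every class
realizable.

A *clamp* is two simultaneous bonds from the position-2 and position-3
hydroxyls of one glucose unit to a shared acceptor. A clamp is `symmetric`
when both contacts are within the census cutoff; asymmetric clamps
(detectable by scanning at a widened cutoff) are kept in `detect_clamps()`
output but flagged, and `census()` totals count symmetric clamps only —
each of which contributes exactly two bonds to its class count.

`count_methyls_near_fc()` uses a **4.0 Å** default proximity cutoff (van
der Waals contact scale) for the methyl-carbon-to-ferrocenyl distance; the
reference analysis leaves this parameter to an appendix, so it is exposed
as an argument rather than hard-coded.

`census()` requires an explicit group label per model (typically
`"best"`/`"worse"`). The published grouping rule for real series lives in
unavailable appendix notes, so the package deliberately does not guess it:
callers supply the split.

## The greedy methylation tree

The tree engine explores methylation states under a pluggable **energy
oracle**: any deterministic function returning component heats of
formation (kJ/mol) for a state. The complexation energy is

$$\Delta E = E_\text{assembly} - E_\text{guest} - E_\text{CD1} [- E_\text{CD2}],$$

negative meaning stabilization. Starting from a generation-0 state (the
winner, per insertion combination, of `select_g0()` over the six
well-defined methylation patterns 2-Me, 3-Me, 6-Me, 2,3-, 2,6-, 3,6-diMe),
each generation inverts every site of the current expansion node — exactly
21 children per generation for 1-CD systems, 42 for 2-CD — and the
lowest-ΔE child becomes the next expansion node. ΔΔE (`deltadelta`) is
recorded for every non-root node as its ΔE minus its parent's.

Open choices, and how they were resolved:

- **Stopping rule.** Reference series report trees whose maximum
  generation exceeds the best generation by up to 4, implying search
  continued past the optimum, but no explicit criterion. The engine stops
  after `patience` consecutive generations without improving the best ΔE
  seen (default **patience = 4**, the largest observed max-minus-best gap),
  or at `max_generations`.
- **Ties.** Equal-ΔE children resolve to the lowest site id; a tie for the
  tree-wide best node resolves to the lowest id with a warning. Both rules
  are deterministic and order-independent.
- **Revisits.** States reached twice are re-evaluated, not cached, so node
  counts mirror evaluations performed; oracles are required to be pure, so
  this changes cost, never results.
- **Determinism.** With a fixed oracle, `run_tree()` is reproducible
  node-for-node; ids are assigned sequentially in creation order from
  `id_base`.

Greedy search is provably optimal on separable (independent-site)
landscapes — each generation's best inversion is a globally correct move —
and this is tested against the closed-form optimum over 100 random
landscapes. On epistatic landscapes greedy is a heuristic; the test suite
bounds it against exhaustive enumeration over 2¹² states.

`oracle_from_table()` wraps a recorded state→energy table (for example a
database export) as an oracle, so recorded series can be replayed through
the same engine.

## Series statistics

`summarize_series()` defines the **improved set** as experiments with
ΔE strictly below the G0 value. Average methylation (mean methyls per
glucose, i.e. methyl count / 7) is computed over that set, per CD slot for
2-CD series; the methylation domain is the min–max rate over the set,
pooled across slots. `n_free_cds` counts distinct per-CD state vectors
over the whole series with the two slots of a 2-CD model pooled: once
freed from the assembly, each CD is a candidate CD in its own right, and
published distinct-CD counts sit far below 2× the sample counts, which is
consistent with pooled deduplication.

## Binding analytics

**Benesi–Hildebrand.** The 1:1 isotherm
$\Delta A = \varepsilon_c l [S] K_a [CD_0] / (1 + K_a [CD_0])$
linearizes exactly to
$[S]/\Delta A = \frac{1}{\varepsilon_c l K_a}\cdot\frac{1}{[CD_0]} + \frac{1}{\varepsilon_c l}$,
so `bh_fit()` runs *unweighted* OLS on the transformed variables — the
double-reciprocal line as practitioners fit it — and returns
$K_a = \text{intercept}/\text{slope}$, $\varepsilon_c l = 1/\text{intercept}$.
For an isomer mixture the recovered $K_a$ is the harmonic mean of the
individual constants. The transform concentrates absorbance noise on the
largest $1/[CD_0]$ points, so the homoscedastic OLS covariance understates
the intercept error several-fold; the reported `ka_stderr` therefore
propagates a heteroscedasticity-robust HC3 covariance through the delta
method. Under the generator's noise model this brings two-standard-error
coverage of the true constant from ~3% to ~98%. Fits with non-positive
slope or intercept have no real $K_a$ and raise an error.

**Phase solubility.** `classify_phase_solubility()` fits
$S = a + b[CD] + c[CD]^2$ and calls the diagram **Ap** when $c$ is
significant (two-sided t-test, α = 0.05) and positive, **AN** when
significant and negative, **AL** when only the positive linear term is
significant, and **flat** otherwise. "Significantly greater than zero" is
implemented as the standard two-sided p-value plus a sign check; this
halves the one-sided type-I rate and keeps miscalls of linear diagrams as
Ap at ~2.5%, comfortably inside a 5% budget. Noiseless profiles have zero
residual variance and undefined t-statistics; they are classified
deterministically from the coefficients' contribution to the curve at the
grid scale (relative threshold 10⁻⁹).

**NBO bookkeeping.** `sum_nbo_contributions()` adds per-interaction E⁽²⁾
stabilization energies and reports kJ/mol and kcal/mol (factor 4.184
exactly). The published contribution tables for the two Fe⋯H–O clamp
contacts ship as `succferr_nbo_contributions()`; the published per-series
tree statistics as `succferr_series_table()`.

## What the synthetic generators emulate — and what they do not

`make_geometry()` builds stylized fixtures: seven rigid pseudo-glucose
fragments on a ring of radius 6 Å (each with position-2/3/6 oxygens plus
ether and anomeric oxygens), and a guest with an Fe atom and small carbon
ring, two phenol O–H groups and two imide carbonyls. Planted contacts are
realized by placing the donor hydrogen on the line to the acceptor at the
exact requested distance (verified to 10⁻⁶ Å); all unplanted donor/
acceptor pairs are laid out several Å apart. These are geometric test
articles, not conformers: bond lengths within fragments, ring pucker, and
sterics are not modeled, so passing tests demonstrate correctness of
*detection and bookkeeping*, not chemical realism of any geometry.

`make_oracle()` realizes an additive landscape (per-site terms + sparse
pairwise interactions + a clamp bonus applied while a designated unit's
2/3 sites are both unmethylated) on top of constant component energies, so
`delta_e()` recovers the planted landscape exactly. The clamp bonus
default magnitude used in examples and acceptance runs is 139 kJ/mol — the
scale of the published clamp-formation anomaly — planted so the engine's
ΔΔE ranking must rediscover it. Real PM3 landscapes are not separable and
not additive; the synthetic ones exist to give tests exact expected
values.

`make_titration()` draws from the exact 1:1 isotherm with additive
Gaussian absorbance noise on an 8-point grid spanning 2×10⁻⁶–2.5×10⁻⁴ M
(micromolar UV-titration range), guest concentration 2.5×10⁻⁵ M and
εc·l = 2×10⁵ M⁻¹, with the planted constant defaulting to 50.618 M⁻¹.
The default noise (`noise_sd = 2.5e-7` absorbance units) was calibrated
once so the fitted-Ka sampling spread is ±10% at this design. Real
titrations add baseline drift and wavelength error that this model omits.

All generators are bit-reproducible for a fixed seed and restore the
caller's RNG state.

## Problem sizes

The shipped test-suite and acceptance-script sizes are: 500 seeded
titration replicates for Ka recovery; 100 random separable landscapes for
greedy optimality; 200 random geometry fixtures (≤ 500 atoms each; 1- and
2-CD) for detector/brute-force agreement; 1000 seeded linear profiles for
the curvature type-I rate; 2¹² exhaustive states for the epistatic bound.
These sizes give stable rates (binomial SE ≤ 2%) while keeping a full run
in tens of seconds.

## Known limitations

- Quantum-chemical evaluation (PM3/DFT/NBO) is out of scope by design; the
  oracle contract is the seam where such engines plug in.
- No automatic bond or ring perception; models without a sidecar cannot be
  analysed.
- The best/worse census grouping used in published series tables is not
  reproduced (rule unavailable); `census()` takes explicit labels.
- Greedy trees give no optimality guarantee on epistatic landscapes; the
  reported best is a lower bound certificate only on separable ones.
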