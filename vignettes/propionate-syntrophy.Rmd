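---
title: "Thermodynamics and community reconstruction of syntrophic propionate degradation"
author: "propsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics and community reconstruction of syntrophic propionate degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propsyn)
```

## The problem

Propionate is a key intermediate of anaerobic digestion and a classic
bottleneck of biogas reactors: its oxidation to acetate, bicarbonate and
hydrogen,

$$\mathrm{propionate^- + 3\,H_2O \rightarrow acetate^- + HCO_3^- + H^+ + 3\,H_2},
\qquad \Delta G^{0\prime} = +76.1\ \mathrm{kJ},$$

is endergonic under standard conditions and only proceeds when partner
organisms keep the hydrogen partial pressure ($p_{H_2}$) low. The partners
are hydrogenotrophic methanogens ($4\,H_2 + HCO_3^- + H^+ \rightarrow CH_4 +
3\,H_2O$, $-135.6$ kJ) and acetoclastic methanogens ($acetate^- + H_2O
\rightarrow CH_4 + HCO_3^-$, $-31.0$ kJ). Two further reactions can buffer
$p_{H_2}$ in either direction: syntrophic acetate oxidation (SAO,
$acetate^- + 4\,H_2O \rightarrow 2\,HCO_3^- + 4\,H_2 + H^+$, $+104.6$ kJ)
and its exact reverse, autotrophic homoacetogenesis (AHA, $-104.6$ kJ).

This package does two things:

1. **Bioenergetics.** It evaluates the transformed Gibbs free energy
   $\Delta G' = \Delta G^{0\prime} + RT \ln Q$ of these reactions under
   arbitrary digester conditions, sweeps $p_{H_2}$, solves crossover points
   ($\Delta G' = 0$) in closed form, and reports the "hydrogen window" in
   which a producing/consuming pair is simultaneously exergonic.
2. **Community reconstruction.** It re-implements, in silico, the classic
   clone-library workflow used to follow propionate-degrading enrichment
   consortia over time: domain-specific PCR with degenerate primers, ARDRA
   (restriction-fingerprint) grouping of clones, identity/coverage
   clustering of representative sequences, species/genus taxonomy
   assignment, and community-level analytics (dominance filtering, guild
   summaries, succession trends, degradation verdicts). A seeded generator
   supplies mock data with the statistical structure this workflow assumes,
   so every stage is testable without external databases.

## The thermodynamic model

`delta_g_prime()` implements

$$\Delta G' = \Delta G^{0\prime} + RT \sum_i \nu_i \ln a_i$$

with $R = 8.314\ \mathrm{J\,mol^{-1}\,K^{-1}}$ and signed stoichiometric
coefficients $\nu_i$ (negative = consumed). Conventions, chosen to match
the published sweep:

* **Prime convention.** The proton activity is referenced to $10^{-7}$, so
  the proton term vanishes at pH 7; water has activity 1; solutes are in
  mol/L against a 1 mol/L standard state; gases in atm against 1 atm.
  Activity coefficients are 1 — no ionic-strength (Davies) corrections and
  no CO$_2$/HCO$_3^-$ speciation.
* **No van 't Hoff correction.** $\Delta G^{0\prime}$ constants are used as
  tabulated; temperature enters only through $RT \ln Q$. This matches the
  published integer table at 37 °C; it would bias results at temperatures
  far from the tabulation.
* **Reference conditions.** `digester_conditions()` fixes 310.15 K, 1 mmol/L
  acetate and propionate, 20 mmol/L bicarbonate, 0.6 atm CH$_4$, pH 7 —
  the mesophilic-digester condition set of the published sweep.

The registry constants (+76.1, −135.6, −31.0, +104.6, −104.6 kJ) were
locked only after verifying, with an independent term-by-term evaluation,
that they reproduce all 40 printed sweep cells within ±1 kJ at integer
rounding. Two internal consistency identities are asserted every time the
registry loads: AHA is the exact negation of SAO, and SAO combined with
hydrogenotrophic methanogenesis equals acetoclastic methanogenesis in both
stoichiometry and $\Delta G^{0\prime}$ (104.6 − 135.6 = −31.0).

Crossovers are solved analytically: with $a$ the H$_2$-independent part of
$\Delta G'$ and $\nu$ the H$_2$ coefficient, $\Delta G'(p_{H_2}) = a + \nu
RT \ln p_{H_2}$ has the unique root $p_{H_2} = \exp(-a/(\nu RT))$. Root
bracketing (`uniroot`) is retained only as a test oracle. Under the
reference conditions the SAO crossover lands at $4.96\times10^{-5}$ atm
(published as $5\times10^{-5}$), and the propionate-oxidation /
hydrogenotrophic-methanogenesis window is $(4.6\times10^{-6},\,
2.0\times10^{-4})$ atm:

```{r window}
reg <- std_reactions()
h2_crossover(reg$sao, digester_conditions())
h2_window(reg$propionate_oxidation, reg$hydrogenotrophic_methanogenesis,
          digester_conditions())
```

Display rounding for the sweep table is nearest-integer, ties away from
zero, as printed tables do; stored cells are unrounded.

A documented discrepancy: the literature quotes $-25.2$ kJ for propionate
oxidation combined with $0.75\times$ hydrogenotrophic methanogenesis, while
the registry constants give $-25.6$ kJ ($76.1 - 0.75 \times 135.6$). The
same source's $-56.6$ kJ for the complete conversion is exactly consistent
with $-25.6 - 31.0$, so the $-25.2$ appears to carry source rounding; the
package reports the algebraic value and treats $-56.6$ as the anchor.
Similarly, the complete-conversion equation is reported here in its exact
net form (acetate cancels between oxidation and acetoclastic
methanogenesis).

## The in-silico clone-library workflow

**Primer matching** (`find_primer_sites()`) is IUPAC-compatibility
matching: two letters match when their base sets intersect. The primer's
3'-terminal base must always match — a polymerase cannot extend a
mismatched 3' end — and the default mismatch budget is 0. Both strands are
scanned. Coordinates throughout the package are 1-based inclusive
intervals, the R/Bioconductor convention.

**PCR** (`simulate_pcr()`) pairs each forward site with the nearest
downstream reverse site on the opposite strand and keeps products within
length bounds. Products include both primer regions, as cloned inserts do.
No melting-temperature or cycling simulation is attempted.

**ARDRA** (`digest()`, `gel_bin()`, `group_profiles()`): molecules are
linear; cut positions are the union over enzymes of site start + cut
offset, deduplicated; fragment lengths always sum to the input length. All
five packaged enzymes (HhaI, HinfI, HaeIII, SmaI, XhoI) have palindromic
recognition sites — asserted at registry load — so one-strand scanning
finds every double-strand site. Gel binning emulates 2% agarose: fragments
below 50 nt are invisible, and bands closer than 5% of the larger length
merge (both parameters are arguments; the source workflow never stated a
resolution criterion, so these defaults are package decisions). Note that
sticky-end cutters shift fragment ends by their overhang (2–4 nt) between
the two strands; this is invisible at gel resolution and immaterial after
binning, but digest patterns of a sequence and its reverse complement are
byte-identical only for blunt cutters.

**Clustering** (`pairwise_identity()`, `cluster_sequences()`) follows
BLASTclust semantics: single-linkage components of the graph with an edge
wherever identity ≥ 97% and coverage ≥ 80% in either query direction.
Alignment is semi-global (free terminal gaps), the stable choice for clone
fragments that read into a gene from one end; identity excludes
terminal-gap columns from its denominator and counts internal gaps as
mismatches. The identity threshold is inclusive (≥ 97) for clustering but
strict (> 97) for species-rank taxonomy assignment, mirroring how each is
conventionally phrased. The historical two-pass 5'/3' resequencing scheme
collapses to one clustering pass over whichever read set is supplied;
running `cluster_sequences()` twice on the two read sets reproduces the
two-pass behaviour. Chimera removal is an upstream, external step: the
package accepts pre-filtered sequences.

**Community analytics** (`build_count_matrix()` and friends): the
dominance rule keeps a cluster that is detectable in all three timepoint
samples of a consortium or reaches ≥ 8% of a clone library in at least one
sample. The proportion denominator is the number of clones sequenced in
that library — published tables list only dominant clusters, so totals are
carried separately; the packaged fixtures use the nominal library size of
60 bacterial (12 archaeal) clones per sample. Trend calls require a strict
change in at least one step (ties alone give `"none"`). A consortium
classifies as a positive degrader when its final propionate concentration
is at most 10% of the initial one — the published data give verdicts, not
a rule, and this default reproduces all four verdicts (positive for Ap1a,
N12, Wp2a; negative for G12) with a wide margin on either side (4% vs
92% residual).

## What the synthetic generator emulates

`make_reference_community()` builds full-length (default 1500 nt) marker
genes carrying the forward primer site at the 5' end and the reverse
complement of the reverse primer at the 3' end. Taxa are derived from one
random ancestor by substituting disjoint position sets, so pairwise
divergences are exact by construction ($2k/L$, just above the requested
`between`, default 0.10); primer sites are never mutated, reflecting the
conservation universal primers rely on. The mutation model is independent
uniform substitution without indels, which keeps identity arithmetic exact
for tests; an indel-free model is the main idealisation relative to real
16S data.

`sample_clone_library()` draws clone taxa multinomially from a
timepoint's composition (library size 60, the study's cloning depth),
applies within-taxon substitutions at rate `within` (default 0.02 for
generation; round-trip tests use 0.01, under the 3% within-cluster bound),
and cuts each clone's single-pass read as a 5'-anchored window of length
uniform in 747–1141 nt. Anchoring at the 5' end emulates vector-primer
Sanger reads that cover one end of the insert; it also means two reads of
one taxon always overlap, as the real 5'-end clustering pass assumed.
ARDRA operates on the full clone insert (colony-PCR product); only the
read enters clustering, exactly as in the wet workflow.

`simulate_degradation()` produces first-order decay
$c(t) = c_0 e^{-r\,\max(0, t-\mathrm{lag})}$ sampled at days 0/14/39/56
(the study's schedule), with defaults $c_0 = 25$ mmol/L and $r = 0.06$/day
— a realistic mesophilic batch rate that empties the substrate within the
8-week experiment. A failed consortium keeps its substrate: the rate is
forced to zero and only small lognormal measurement jitter (sd 0.03)
remains.

`run_round_trip()` chains PCR → ARDRA → grouping → clustering → count
matrix and scores the result against truth labels: recovered cluster
count, membership agreement under a greedy one-to-one cluster↔taxon
matching, and per-sample total-variation distance to the true composition
(mass in unmatched clusters counts as error). At $n = 60$ clones and five
taxa, multinomial noise alone contributes a TV distance of about 0.10, so
the pipeline target of a mean TV below 0.15 leaves only modest room for
reconstruction error — passing it indicates near-perfect clustering, not
merely generous tolerance.

What passing these tests does **not** show about real data: no chimeras,
no indels or sequencing error profiles, no secondary-structure or
GC-content realism, no primer-template mismatch biases, and taxonomy
assignment against a user-supplied reference set rather than a curated
database.

## Numerical and scale choices

* Random draws are seeded per dataset; operation-level sub-streams derive
  deterministically from the master seed, and generators restore the
  caller's RNG state.
* Stoichiometric cancellation uses a $10^{-12}$ absolute threshold; the
  published coefficients (0.25, 0.75, 1.75, …) are exactly representable.
* Alignment scoring is match +2 / mismatch −1, gap opening 10, extension 4;
  on the indel-free test distributions the optimum is gapless, so identity
  values are insensitive to the gap parameters.
* Property tests run at desk scale chosen for tight feedback: random
  digests up to 5 kb, planted-cluster recovery over 20 seeds at 900 nt
  genes, composition recovery over 20 seeds at one 60-clone library each,
  200-replicate binomial checks for the sampler.

## Known limitations

* $\Delta G^{0\prime}$ constants are fixed at their tabulated reference;
  extrapolation far from 37 °C ignores reaction enthalpies.
* Single-linkage clustering is quadratic in the number of sequences; it is
  meant for clone-library scale (tens to hundreds of representatives), not
  amplicon surveys.
* The gel model bins by length only — no mobility curvature, band
  intensity, or partial digestion.
* Degradation classification is a two-point rule (final vs initial); it
  deliberately ignores lag structure, which `simulate_degradation()` can
  nevertheless generate for stress-testing.
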