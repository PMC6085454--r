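---
title: "Methods: electron balance, doublet fitting and genome screening in ferroco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron balance, doublet fitting and genome screening in ferroco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroco)
```

This vignette is the package's own account of the models it implements, the
assumptions behind them, the parameters that matter, and the places where a
design choice was genuinely open.

## 1. Electron-balance composition of brutto-equations

### Model

Growth on lactate + CO with an Fe(III) mineral is treated as three catabolic
half-reactions running in parallel: lactate oxidation to acetate (4 e⁻ per
mole), CO oxidation (2 e⁻ per mole) with Fe(III) as acceptor, and CO
oxidation with protons as acceptor (hydrogenogenesis, 1 H₂ per CO). Given a
phase summary (*L* mol lactate catabolized, *F* mol Fe(III) reduced, *H* mol
H₂ produced), `compose_brutto()` assigns lactate electrons to Fe(III) first
and closes the ledger

$$4L + 2\,\mathrm{CO} = F + 2\,\mathrm{H_2}$$

so that CO = (*F* − 4*L*)/2 + *H*. The remaining coefficients follow from
element conservation: H₂O = CO₂ = CO + *L*, Fe²⁺ = H⁺ = *F*, acetate = *L*.
All five balances (C, H, O, Fe, charge) then hold identically;
`check_balance()` recounts them and is used as an internal invariant
(property-tested over 1000 random feasible inputs).

### Assumptions and conventions

* **Catabolized lactate equals acetate formed.** Roughly half of consumed
  lactate is assimilated as carbon; assimilated lactate carries no catabolic
  electrons and is excluded from the ledger. This convention is what makes
  per-lactate CO coefficients like 30:1 and 270:1 arise from measured
  concentrations.
* **One electron per Fe atom**, regardless of the mineral product (magnetite
  vs siderite): the ledger counts Fe³⁺ → Fe²⁺ only.
* Coefficients are kept as plain numerics; with integer inputs all derived
  coefficients are exact (halves at worst), so no rational arithmetic layer
  is needed. Display rounding happens only in `print()`.
* `compose_brutto()` refuses *F* < 4*L* ("donor electron excess"): measured
  iron cannot absorb the lactate electrons, so the phase summary is
  inconsistent. In `partition_from_timeseries()` this same situation can
  arise from measurement noise; there the lactate coefficient is clipped to
  *F*/4 (the surplus is treated as assimilated carbon) instead of aborting
  the whole trajectory — a deliberate robustness choice for noisy inputs,
  while the strict error remains in force for direct calls.

### Phase boundaries

User-supplied breakpoints take precedence; `detect_breakpoint()` is a
convenience that exhaustively fits a continuous two-segment piecewise-linear
model to the Fe(II) curve (knot at each interior sample) and takes the
SSE-minimising knot. A two-phase call requires a ≥20% relative SSE
improvement over a single line (`tol = 0.2`); below that, or for an exactly
linear curve, the result is flagged "no distinct phases". The tolerance is
deliberately coarse — the quantity is a reading aid, not an estimator with
coverage guarantees.

The per-phase report deliberately shows both the phase-wise
lactate→acetate conversion (≈77% in the first phase of the ferrihydrite
scenario) and the cumulative one (≈48%); the two are not reconciled into a
single number because they measure different windows of the same trajectory.

## 2. Mössbauer doublet model and fitting

### Forward model

A room-temperature paramagnetic spectrum is modelled in the thin-absorber
approximation as

$$I(v) = B\left(1 - \sum_k \frac{A_k}{2}\left[\mathcal{L}(v;\,\delta_k -
\Delta_k/2,\,\Gamma_k) + \mathcal{L}(v;\,\delta_k + \Delta_k/2,\,
\Gamma_k)\right]\right)$$

with unit-area Lorentzians $\mathcal{L}$, baseline $B$ counts per channel,
and per-doublet isomer shift δ, quadrupole splitting Δ, linewidth Γ and
integrated area $A$ (all velocity-domain quantities in mm/s). Counting noise
is Poisson per channel. The default grid is ±4 mm/s in 512 channels — wide
enough for ferric and ferrous silicate doublets and siderite. Under the
equal recoil-free-fraction assumption, relative subspectrum areas equal
relative Fe-atom fractions; `site_fractions()` is exactly that
normalisation.

### Fitting

`fit_spectrum()` minimises Poisson-weighted squared residuals
(weights $1/\sqrt{y}$) with Levenberg–Marquardt (`minpack.lm`). Doublet
fitting is multimodal, so the fit is multi-started from combinations of six
deterministic (δ, Δ) anchors spanning the ferric silicate, ferrous silicate
and siderite regions plus two generic fillers; the best weighted SSE wins,
ties broken by the smaller total linewidth. An early exit on "good enough"
chi-square was tried and removed: with a weak doublet whose lower line is
buried under the ferric absorption mass, the first converged start can be a
degenerate pairing that is statistically acceptable but physically wrong;
running all starts and keeping the SSE optimum resolves it.

The conventional **equal-linewidth constraint** shares one Γ across all 2*n*
lines; the unconstrained model gives every Lorentzian line its own width, so
the constraint removes 2*n* − 1 parameters. Parameter 1σ uncertainties come
from the inverse Hessian at the optimum scaled by the residual variance;
when the Hessian is not invertible the uncertainties are flagged
unavailable rather than silently zeroed.

Initial areas are seeded from the observed integrated absorption; bounds
keep areas non-negative, Γ ∈ [0.05, 2] mm/s and δ ∈ [−3, 3] mm/s. The
baseline is fitted on a log scale within ±e of the 98th counts percentile.

### Phase library

The (δ, Δ) assignment windows — siderite δ ∈ [1.10, 1.35], Δ ∈ [1.60, 2.05];
ferrous octahedral silicate δ ∈ [1.00, 1.30], Δ ∈ [2.10, 3.00]; ferric
octahedral silicate δ ∈ [0.20, 0.50], Δ ∈ [0.30, 1.40] mm/s — are
conventional room-temperature ranges, applied first-match-wins, and are an
argument everywhere they are used: they are a reading of the literature,
not a fitted quantity.

### Presets

The three glauconite presets encode only the measured area fractions as
ground truth (ferrous share 2.2% initially, 5.7% at 166 h, and a 3.9%
siderite component among four doublets at 960 h). Everything else — the
split of the ferric area between two doublets (0.40 and 0.95 mm/s
splitting), Γ = 0.30 mm/s, and a total absorption of 0.12 mm/s (a few
percent dip at baseline 10⁶ counts) — is a documented default chosen once to
look like a realistic silicate spectrum, and overridable.

### What recovery tests show — and don't

At baseline 10⁶ counts the 3.9% siderite doublet is a ≈0.3% absorption dip
against ≈0.1% per-channel noise; the acceptance-level check verifies that
the *mean* refitted fraction over 20 seeds stays within ±1.3 absolute
percent of truth (and ±1.0 for the 5.7% ferrous share). This demonstrates
estimator correctness within the model class. Real spectra add effects the
simulator does not emulate: thickness saturation, baseline curvature,
site-dependent recoil-free fractions and non-Lorentzian broadening — so
passing these tests says nothing about those systematics.

## 3. Genome screening

* **Degenerate consensus scanning** is bitmask matching: each base is a
  bit-set, a pattern position matches when pattern∩subject ≠ ∅. A subject
  `N` carries its own bit, included only in the pattern letter `N` — so `N`
  in a genome never satisfies a fixed or partially degenerate pattern
  letter. Minus-strand hits are reported at the plus-strand coordinate of
  the window start. The implementation is checked against an independent
  PCRE regex matcher and against the analytic random-hit rate
  ((1/4)⁷(1/2)³ per strand-position for the CooA box) on a 1-Mb sequence.
* **Operon inference** groups same-strand, same-contig genes with
  intergenic gaps ≤ `max_gap`. The default of 60 bp sits just below the
  70–100 bp band that marks genes sitting alone in their operons.
  Site-to-operon assignment uses a 300 bp upstream window (a typical
  bacterial promoter region; the value is a configurable convention, not an
  inference), excludes hits inside coding regions, and resolves ties
  nearest-first, then strand agreement, then coordinate.
* **Heme census**: strict policy counts non-overlapping left-to-right
  C-x(2)-C-H; extended adds x(3) and x(4) spacers, shortest spacer first at
  each start. `X` never matches. The counter is verified against a naive
  scan over every sequence of length ≤ 8 on the {C, A, H} alphabet. The
  strict CXXCH count is a motif census, not a domain annotation: on real
  proteomes it can differ by a few genes from Pfam-domain-based multiheme
  calls, which is why both policies are reported side by side.
* **Alignment-based operations** delegate Needleman–Wunsch with affine gaps
  to `Biostrings::pairwiseAlignment` (BLOSUM62, gap open 10, extend 0.5 by
  default). Percent identity is matches over alignment columns after
  excluding terminal gap runs; coverage is each sequence's share of that
  core. Reciprocal best hits use a shared-5-mer prescreen (top 3 candidates
  aligned) and default floors of 40% identity / 70% coverage — conservative
  orthology thresholds for a within-species comparison.
* **ANI** follows the fragment protocol: 1020-bp query fragments, located
  in the subject by exact 13-mer seed voting (one Aho–Corasick pass over
  all seeds), aligned global-local to the voted window, kept if ≥30%
  identity over ≥70% of their length; the report is the mean of the two
  directional means. Fragments with ≥97% ungapped identity on the voted
  diagonal skip the alignment — at that identity the affine gap cost
  guarantees the gapless alignment is optimal, so the shortcut is exact.
  Self-ANI is exactly 100; a 0.3% substitution load gives ≈99.7, matching
  the expected identity 100(1 − p); 10% divergence falls below the 95%
  species threshold.

## 4. The synthetic-data layer

`simulate_culture()` integrates a deliberately simple flux model (explicit
Euler, 0.5 h step): Monod uptake of CO and lactate scaled by cell density,
logistic growth toward a carrying capacity with yield proportional to
electron flux, a CO-electron partition that switches from its phase-1 to its
phase-2 value when the medium potential crosses a threshold, and a redox
potential that interpolates linearly from the initial value toward a floor
as Fe(II) accumulates (endpoints −90 → −360 mV for ferrihydrite, −90 → −520
mV for glauconite). Noise, when requested, is Gaussian and relative, applied
after integration — so the noise-free signal satisfies the electron ledger
exactly at every step, which is the invariant the tests lean on.

The preset parameters were calibrated once so the noise-free ferrihydrite
run reproduces the study conditions it emulates: ≈2.3 mM lactate consumed
with ≈1.1 mM acetate formed, ≈77% phase-1 conversion, a phase switch near
24 h, and partitions 13/30 then 3/270; the glauconite run produces 1.42 mM
Fe(II) with no acetate, stops reducing iron when CO runs out, and ends at
−520 mV. The simulator emulates endpoint fidelity and phase structure, not
the exact curve shapes of real growth data (no lag phase, no cell lysis, no
gas–liquid partitioning — all gas pools are liquid-phase mmol-equivalents).

`generate_strain_pair()` plants, on one strand of a single contig: the
three-operon coo cluster in the order
*cooA* | *cooS cooC* | *cooM K L X U H hypA cooF cooS cooC* with one
concrete consensus instance ~60 bp upstream of each CODH operon; 30 shared
multiheme proteins with configured heme counts (default includes a 15-heme
and a 6-heme protein); and one 17-heme protein in strain B only. Strain B's
shared proteins carry a 0.5% substitution load applied only to non-C/H
residues, which provably preserves every heme motif while keeping pairs at
99–100% identity. Accidental CXXCH motifs and consensus instances are
scrubbed from background proteins and planted-site neighbourhoods
respectively, so generator bookkeeping is exact ground truth; random
consensus hits elsewhere in the genome are left in (they occur at the
analytic rate and the upstream-window filter must reject them).

## 5. Problem sizes and runtime choices

The test suite simulates spectra at 512 channels and fits ≤4 doublets; the
acceptance-level recovery uses 20 noisy replicates per preset. The
strain-pair default is 40 background CDS plus 43 planted genes (~75 kb
genomes), large enough for every screen to act on non-trivial input while
the full suite stays in the minutes range. ANI calibration runs on 2-Mb
random genomes (≈1960 fragments per direction); the end-to-end replay uses
smaller genomes for its ANI stage (200 kb by default, configurable), since
it checks wiring rather than calibration.

## 6. Known limitations

* The balance module is bookkeeping, not thermodynamics: no ΔG or Nernst
  feasibility, no intracellular flux model of the Wood–Ljungdahl network.
* The Mössbauer module fits paramagnetic doublets only — no magnetic
  sextets, no transmission-integral thickness correction, no
  temperature-dependent recoil-free fractions.
* The genome module does no homology search, domain calling or phylogeny;
  the heme census is a motif count, and the strain comparison is
  reciprocal-best-hit only.
* The culture simulator's growth law is a convenience; its parameters are
  tuned to endpoints, and nothing about curve shape should be read as a
  biological claim.
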