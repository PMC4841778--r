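---
title: "Models and methods for 13C tracer analysis of exosome-driven metabolic rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for 13C tracer analysis of exosome-driven metabolic rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoflux)
```

# The scientific setting

Cancer-associated fibroblasts secrete exosomes that, once taken up by
cancer cells, suppress mitochondrial oxidative phosphorylation and push
central carbon metabolism toward glycolysis and glutamine-dependent
reductive carboxylation. They also deliver intact metabolites — amino
acids, TCA-cycle intermediates, lipids — directly to the recipient
cell. Both claims rest on a chain of ¹³C tracer computations: mass
isotopologue distributions (MIDs) measured by GC-MS, natural-abundance
correction, mean-enrichment summaries, isotopologue spectral analysis
of fatty-acid labeling, and extracellular-flux arithmetic. `exoflux`
implements that chain as reusable, tested components, together with a
generative model that lets every stage be validated against known
ground truth.

# MIDs and natural-abundance correction

A MID is the vector of relative abundances of M+0 … M+N for a fragment
whose backbone carries N tracer-labelable carbons. Raw intensities are
proportionally normalized (`normalize_mid()`). Mean enrichment,

$$\mathrm{ME} = \frac{\sum_{i=1}^{N} i\, M_i}{N},$$

is the average fraction of backbone carbons carrying label; it is
linear in the MID and bounded by [0, 1].

The measured fragment contains atoms beyond the tracer-labelable
backbone — derivatization carbons, H, N, O, Si, S — whose natural heavy
isotopes shift mass exactly like tracer does. `build_correction_matrix()`
constructs, column by column, the probability that a molecule with *i*
tracer carbons appears at nominal shift *j*: the convolution of (a) the
binomial labeling of the *i* tracer positions at the stated tracer
purity, (b) natural ¹³C in the remaining backbone positions, and (c)
the natural isotope distributions of all other atoms (IUPAC
abundances, `iupac_isotopes()`; overridable via a YAML table). Shifts
beyond the measured window are truncated, so column sums may fall below
one — no renormalization hides that loss.

`correct_natural_abundance()` inverts the convolution by non-negative
least squares (Lawson–Hanson via `pracma::lsqnonneg`), then
renormalizes. NNLS keeps corrected fractions non-negative so that
downstream ratios (M4/M5 citrate, enrichment ratios) remain
well-defined; the price is a small upward bias on isotopologues whose
true abundance is near zero when spectra are noisy (see *Known
limitations*). On noise-free spectra the correction inverts the forward
model to better than 1e-10, which the test suite verifies over random
fragments and MIDs.

Tracer purity defaults to 0.99 per labeled position wherever a
correction or template is built; commercial tracers are rarely purer,
and no batch certificate is available to be more specific. The flag is
explicit everywhere so a user with a certificate can override it.

Whether a given published figure was natural-abundance corrected is
often unknowable; the pipeline therefore never guesses — correction is
an explicit step (`correct_mid_table()`) that stamps a `corrected` flag
which downstream consumers check.

# Isotopologue spectral analysis

ISA treats the lipogenic acetyl-CoA pool as a two-component mixture

$$X = D\,T + (1-D)\,N,$$

where T is the acetyl MID produced from the tracer (both acetyl
carbons labeled for uniformly labeled glucose, glutamine, pyruvate, or
acetate, degraded by tracer purity: `tracer_acetyl_template()`), N is
the naturally labeled acetyl MID (each carbon ¹³C at 1.07%:
`natural_acetyl()` ≈ [0.9787, 0.0212, 0.0001]), and D is the tracer's
fractional contribution. A fatty acid of 2n carbons assembles n acetyl
units drawn independently from X, so its de novo MID f(X) is the
n-fold self-convolution of X — the multinomial model. The measured pool
mixes newly made and pre-existing molecules:

$$P_{M+x} = g\,f_{M+x}(X) + (1-g)\,f_{M+x}(N).$$

One methodological note: a published schematic of this model writes
the M+3 weight as a product of two binomial coefficients
($\binom{8}{5}X_0^5\binom{8}{3}X_1^3 + \dots$), which double-counts
arrangements; the combinatorially consistent weight for a composition
$(n_0, n_1, n_2)$ of 8 units is the single multinomial coefficient
$8!/(n_0!\,n_1!\,n_2!)$. `exoflux` implements the multinomial /
convolution form and the test suite proves it equal to exhaustive
enumeration over all $3^8$ acetyl-unit assignments to below 1e-12.

**Estimation.** For fixed D the model is linear in g, so the optimal g
is a closed-form clipped projection; only D requires numerical search.
`fit_isa()` minimizes the profiled sum of squares over D ∈ [0, 1] with
bounded golden-section/parabolic search multistarted on five
subintervals plus explicit boundary checks. This profile scheme is used
instead of a two-parameter quasi-Newton multistart because the latter
stalls near its convergence tolerance (~1e-6 in the parameters) while
the profile reaches ~1e-8, and noise-free self-consistency at 1e-6 is
part of the estimator's contract. g(t) is fit as a scalar per time
point; no turnover kinetics are modeled, matching single-time-point
sampling designs (72 h for lipids). When replicate MIDs are supplied,
a seeded bootstrap over replicates (default 200 resamples) yields
percentile CIs; D̂ itself is fit on the replicate mean and is invariant
to replicate order. A measured MID indistinguishable from f(N) leaves
g (and hence D) unidentifiable; the fit returns with a
`"g-at-boundary"` flag rather than failing.

Multi-tracer designs (glucose + glutamine + acetate + pyruvate) are
composed as independent single-tracer fits, mirroring per-tracer
experiments; the unaccounted share is 1 − ΣD̂.

# Scalar flux metrics

Under U-¹³C₅ glutamine, the oxidative TCA turn makes M4 citrate
(labeled oxaloacetate + unlabeled acetyl-CoA) while reductive
carboxylation of α-ketoglutarate makes M5 citrate; `citrate_ox_red()`
reads both off the corrected MID and reports M4/M5, with an infinity
sentinel rather than an exception when M5 is zero, because control
conditions can have essentially no reductive flux. The
α-ketoglutarate/citrate pool-abundance ratio (`pool_ratio()`) rises
with reductive carboxylation and is kept as a separate, purely
abundance-based readout.

"Percentage contribution" of a substrate to a downstream metabolite is
not given a formula in most papers; `substrate_contribution()`
operationalizes it as mean enrichment divided by the achievable feed
enrichment (1 for a uniform tracer, 7/12 for the 1:1 U-¹³C₆ / 1-¹³C₁
glucose cocktail), capped at one, with the raw mean enrichment attached
as an attribute so either convention can be audited.

With the 1:1 glucose cocktail, M1 pyruvate can only come from
glucose-6-phosphate that kept its C1 through phosphoglucoisomerase;
oxidative pentose-phosphate routing decarboxylates C1 and erases the
signal. `m1_glycolysis_index()` is therefore just the M1 fraction with
a tracer-identity guard; its interpretation is qualitative and stays in
documentation, not computation.

# Exosome cargo contribution and dosimetry

Producer fibroblasts labeled for 72 h — less than one population
doubling — package partially labeled metabolites into exosomes. The
fraction of a recipient-cell pool supplied by exosomes is estimated as

$$\mathrm{contribution} = \frac{\mathrm{ME}_{\mathrm{cell}}}{\mathrm{ME}_{\mathrm{exosome}}},$$

in which the unknown producer labeling fraction cancels. For essential
amino acids the recipient has no synthetic route, so enrichment above
the source is impossible at steady state: contributions above one are
clipped with a warning. Non-essential metabolites (glutamine included,
despite its conditional essentiality, because glutamine synthetase
exists) may legitimately exceed one and are flagged, never clipped.
When the cell catabolizes the metabolite, measured contribution is a
lower bound on cumulative supply — the simulator's `cargo_turnover`
parameter reproduces exactly this compression and the test suite
asserts the bound. Contributions are computed per replicate and
summarized as the median with a seeded bootstrap CI
(`summarize_cargo_contributions()`), matching small-n (n = 4)
experimental designs.

Dosimetry uses the calibration 4.9 µg exosome protein per 10⁹ particles
and 28 000 particles per producer fibroblast per 48 h.
`particles_from_mass()`, `mass_from_particles()`, and
`caf_equivalents()` compose exactly and let a dose in µg/ml be read as
"producer cells per cancer cell"; the producer yield is an input, not a
derived constant, because the producer count behind published yields is
generally not stated.

# Bioenergetics

A mitochondrial stress test injects oligomycin, FCCP, and an
electron-transport-chain blocker (rotenone and antimycin are treated as
synonyms for the same segment) into a well measured over time.
`derive_bioenergetics()` summarizes each segment by the mean of its
last three measurements (configurable), discarding mixing transients,
and derives per-µg-protein rates: non-mitochondrial OCR (post-block
plateau), basal OCR both raw and corrected (the literature is
inconsistent about whether basal subtracts non-mitochondrial OCR, so
both are emitted), maximal OCR (post-FCCP minus non-mitochondrial),
reserve = maximal − basal exactly, and basal ECAR. Missing segments
disable only the dependent metrics; negative derived rates are floored
at zero with a warning since a biological OCR cannot be negative.

# The synthetic-data generator

`propagate_labels()` runs a steady-state fixed point (tolerance 1e-10,
capped at 10 000 iterations with a diagnostic error) over full
positional isotopomer distributions — 2ⁿ states per n-carbon
metabolite — on a toy atom-mapped network:

* glycolysis: glucose C1–C3 → pyruvate C3–C1 (DHAP arm), C4–C6 →
  pyruvate C1–C3 (GAP arm);
* an oxidative pentose-phosphate shunt (fraction `f_ppp`) that loses
  glucose C1 as CO₂ and yields pyruvate through the GAP arm only;
* PDH (loses pyruvate C1), acetate activation, medium pyruvate uptake;
* an oxidative TCA turn with symmetric succinate/fumarate scrambling
  (the M3 fumarate/malate patterns depend on it);
* a reductive branch (fraction `f_red`): α-ketoglutarate + unlabeled
  CO₂ → citrate, whose cleavage returns M2 acetyl units and M3
  oxaloacetate from M5 citrate;
* glutaminolysis and a lipogenic acetyl-CoA pool assembled from
  per-source routes with configurable shares, feeding palmitate as
  eight acetyl units.

A steady-state fixed point rather than time-resolved ODEs is the right
level of fidelity here because the measurements it emulates are single
late-time-point MIDs; kinetic rate constants would add parameters
without adding testable structure. Carbon maps are explicit, so label
conservation (reactant label = product label + labeled CO₂) is
assertable per reaction, and limiting cases are exact: pure reductive
flux gives M5 citrate = 1 under U-¹³C₅ glutamine, a pure oxidative turn
with unlabeled acetyl-CoA gives M4 citrate = 1, and the 1:1 glucose
cocktail with no pentose-phosphate shunt gives exactly 0.25 M1
pyruvate.

The measurement model forward-convolves each clean MID with its
fragment's correction matrix (the shipped fragment formulas are
representative synthetic stand-ins for instrument-specific TBDMS /
methyl-ester fragments, not certified ones), adds per-isotopologue
Gaussian noise (default sd 0.005), clips at zero — intensities cannot
be negative — renormalizes, and scales by a pool-size-weighted
log-normal total ion current. Output is byte-identical under a fixed
seed; a seed is mandatory for any stochastic run.

Two presets, `"control"` and `"cde"` (exosome-treated), differ only in
the *directions* the biology dictates: the treated preset raises
`f_red`, the glutamine and acetate acetyl shares, the
α-ketoglutarate/citrate pool ratio, and ECAR, and lowers the glucose
acetyl share, medium-pyruvate dilution, and every OCR level. No preset
parameter is calibrated to a published bar height — none are deposited
numerically — so simulator-based checks are directional and
recovery-based, never magnitude-matching. The exosome labeling fraction
after 72 h is fixed at 0.5 (the only constraint available is
"less than one doubling", so the midpoint is used); it cancels from
cargo contributions anyway. Default replicate count is 4 per condition,
mirroring the published experimental design; recovery-style acceptance
checks that need tighter Monte Carlo error run the same generator at
larger sizes (24 simulated replicates for cargo recovery, 50 for noisy
ISA recovery, 300–1000 round-trip draws), stated in the tests and
acceptance script themselves.

# What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes:
steady-state labeling, independent per-isotopologue Gaussian noise,
complete atom maps, a single lipogenic acetyl pool. Real data add
chromatographic interference, non-Gaussian and correlated noise,
incomplete derivatization, compartmentalized acetyl-CoA pools, and
kinetic transients. Passing recovery tests therefore demonstrates that
the estimators are correct implementations of their models, not that
the models capture every feature of real spectra.

# Known limitations

* NNLS correction is biased upward on isotopologues with near-zero true
  abundance in noisy spectra (zero-clipping of noise); at noise sd
  0.005 this contributes up to about one percentage point to small
  enrichment ratios. Averaging replicate spectra before correction
  reduces, but does not remove, this bias — the generator's own
  non-negative intensity clipping produces the same effect at the
  source.
* The network is structural, not calibrated: no published flux values
  exist to fit, so simulated magnitudes mean nothing outside the
  directional and recovery tests they serve.
* Palmitate is modeled strictly as 8 acetyl units (stearate as 9);
  elongation and desaturation beyond that, and acetyl-CoA
  compartmentation, are out of scope.
* High-resolution isotope fine structure and peak integration from raw
  chromatograms are out of scope; inputs begin at integrated
  intensities.
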