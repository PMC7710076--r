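---
title: "Designing and validating species-specific qPCR assays for eDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating species-specific qPCR assays for eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaqpcr)
```

## The problem

Detecting a species from environmental DNA (eDNA) in water requires a
hydrolysis-probe qPCR assay: a forward primer, a reverse primer, and a
dual-labelled probe that together amplify and report a short (100-200 bp)
fragment unique to the target. Designing one is a pipeline: align the
available reference sequences for the target, pick a conserved template,
enumerate primer/probe candidates under thermodynamic and compositional
constraints, screen the chosen triple in silico against non-target
sequences, and finally quantify bench validation — standard curves,
amplification efficiency, limit of quantification (LOQ), panel sensitivity
and specificity — before back-calculating eDNA concentrations in field
samples. `ednaqpcr` implements each of those computational steps with
deterministic, testable code, plus seeded simulators so the whole chain can
be exercised without touching external databases.

## Melting-temperature model

Oligo melting temperatures use the unified nearest-neighbor thermodynamic
parameters (SantaLucia 1998): the duplex enthalpy and entropy are summed
over dinucleotide stacks with terminal A/T (+2.3 kcal/mol, +4.1 cal/mol/K)
and G/C (+0.1, -2.8) initiation penalties, the entropy receives the salt
correction 0.368 (N-1) ln[Na+eq], and

Tm = 1000 ΔH / (ΔS + R ln(CT/4)) - 273.15,

with R = 1.987 cal/(mol K) and CT the total oligo concentration (the /4
convention for primers in excess of template). Divalent cations fold into a
sodium equivalent as [Na+eq] = [Na+] + 120 sqrt([Mg2+] - [dNTP]) (von Ahsen
2001).

The default conditions are `thermo_params(monovalent_mM = 50, divalent_mM =
1.5, dntp_mM = 0.6, oligo_nM = 50)` — the defaults of mainstream
primer-design software. We chose them after observing that, under this
model, they reproduce the published melting temperatures of all nine oligos
shipped with the package to within 0.06 degC (e.g. 59.97 vs a printed 60.0
for the humpback forward primer), whereas a divalent-free condition sits
about 6 degC lower. Published Tm values are still only asserted to a
conservative ±1.5 degC in the tests, since the engine behind any given
printed table is rarely documented. The implementation is verified against
an independent published nearest-neighbor implementation at identical
parameters (values frozen into the test suite).

Tm requires at least 8 bases (shorter oligos are outside the NN model's
calibration) and rejects ambiguity codes. GC content is reported to one
decimal with half-up rounding, matching the convention of published assay
tables (63.64 prints as 63.6).

## Design constraints and selection criteria

`enumerate_candidates()` places every (forward, probe, reverse) footprint
combination on a template and keeps those satisfying all *hard*
constraints: product 100-200 bp, oligo 18-27 nt, primer Tm 58-63 degC,
probe Tm 68-73 degC, GC 35-65%, probe strictly between the primer
footprints. Coordinates are 1-based inclusive; a reverse primer's
coordinate is the plus-strand base paired with its 5' end, so product
length is `R - F + 1` (the convention behind names like `287F`/`437R`).
Probes are emitted on the plus strand only, matching how the shipped
assays' probes are written; probe binding to either strand is still
honoured during screening.

Survivors are scored against eight *soft* selection criteria: primer ΔTm <
5 degC; probe Tm 8-10 degC above the primer mean; no homopolymer run ≥ 4;
no primer 3'-T; primer 3' C/G; ≥ 3 C/G in the 5 terminal primer bases; no
probe 5'-G (fluorophore quenching); probe GC > 50%. Primer-specific rules
must hold for *both* primers to count. Where the probe-ΔTm rule is stated
against "the primers" without naming one, we use the mean of the two primer
Tm values — symmetric, and configurable in `selection_criteria()`.
`score_candidate()` reports each criterion with its measured value, so the
manual triage step of classical design becomes an auditable table.

Ranking is a stable sort: criteria satisfied (descending), then summed |Tm
- optimum|, then summed |GC - optimum|, then product length, with
coordinates as the final tie-break. Enumeration is fully deterministic —
no randomness exists anywhere in the design module.

On a 211-bp test template this exhaustive semantics yields millions of
triples; the implementation scores them vectorised over index triples and
only materialises sequences for the rows returned. Tests verify exact
set-equality against a naive triple-loop oracle on ~174-bp templates.

## Conservation windows and logos

`window_frequencies()` locates an oligo's binding region in each row of an
alignment and tabulates per-column A/C/G/T frequencies over the window —
the numbers behind a sequence logo. Localization tries an exact match, then
one mismatch, then the best ungapped match capped at 30% mismatches. The
cap is our choice: without one, a "best match" always exists and the
biologically meaningful outcome *no contigs found* (a primer region simply
absent from a divergent non-target family) would be unreachable. Reverse
primers are reported 5'→3' in primer orientation (reverse complement of
the plus-strand window). Columns are normalised over observed A/C/G/T only;
gaps do not contribute.

Consensus calling (`consensus_sequence()`) uses a threshold in (0.5, 1],
default 1.0, falling back to the minimal IUPAC code covering the observed
bases; columns gapped in at least half the rows are dropped. The default
reflects the use case: target alignments here are >97% identical, so the
consensus is essentially the majority sequence and the threshold is rarely
stressed.

## In-silico specificity screening

`find_binding_sites()` is an ungapped (Hamming) sliding scan of an oligo
over both strands of a subject; IUPAC codes in the subject match
permissively (the code's expansion must contain the oligo base), ambiguity
in oligos is disallowed. Indels are deliberately not modelled: for 18-27 nt
oligos, substitution mismatches dominate cross-reactivity, and ungapped
screening keeps the search exact and fast. This is a documented limitation
— an off-target with a 1-nt bulge in the binding site would be missed.

`predict_amplification()` combines per-oligo hits the way database hits
are combined when checking an assay against a sequence collection: positive
iff a forward site on the plus strand and a reverse site on the minus
strand flank a product of allowed length with a probe site strictly inside,
each within its mismatch budget (default 5 per oligo — the conventional cap
when compiling mismatch tables). Orientation and product-length enforcement
are explicit package choices; a `require_three_prime_match` toggle exists
(default off) because polymerase extension is 3'-sensitive but hit-combining
workflows traditionally ignore it. Among multiple site combinations the
minimal-total-mismatch one is reported, ties broken by shorter product and
left-most position.

## Plate analytics

The plate contract is a CSV with `sample_id, role, replicate, cq,
known_conc_pg_per_ul, template_ul`; an empty or `ND` Cq is a non-detect.
Cq values must lie in (0, 40] by default. NTC wells with any Cq raise a
contamination warning and never enter any computation.

*LOQ*: the lowest standard concentration at which every replicate has a
Cq, such that every higher concentration is also fully detected (the
downward-consistency stop). Consistency is evaluated within the plate;
cross-plate consistency is the caller's responsibility. Units follow the
standards (pg gDNA/µL extract).

*Standard curve*: ordinary least squares of Cq on log10(concentration) —
Cq as response is the universal qPCR convention, giving slope ≈ -3.32 at
100% efficiency since efficiency = 10^(-1/slope) - 1. Detected replicates
at or above the LOQ enter the fit; partially detected points below it are
excluded because dropout censors the high-Cq tail and biases the slope. A
positive slope flags the curve invalid. At least three distinct usable
concentrations are required.

*Calls*: a replicate with Cq below the LOQ Cq (the mean Cq at the LOQ) is
a quantifiable positive; ND is negative. A replicate amplifying *above*
the LOQ Cq is, by default, treated as a detection below the limit of
quantification (BLOQ), configurable to negative — the rule is explicit
here because validation datasets may simply never exercise it. Sample
status aggregates replicates: all quantifiable → `quantified`; any
detection → `BLOQ`; none → `ND`.

*Sensitivity / specificity*: TP/(TP+FN) and TN/(TN+FP), rounded half-up to
integer percent for parity with published validation tables.

*Quantification*: each quantifiable replicate is inverted through the
curve, `10^((Cq - intercept)/slope)` pg/µL of template, then scaled by the
dilution factor and extract volume and divided by the filtered water
volume to give pg per mL of water. The 95% interval is Student-t on the
replicate-level concentrations (n-1 df) — a pragmatic choice; it ignores
curve-parameter uncertainty, which is typically dominated by replicate
scatter at field concentrations.

## Synthetic data

Two seeded generators make the pipeline testable end to end.
`generate_panel()` plants an F / probe / reverse-complemented-R cassette
with controlled per-oligo mismatch counts and spacer lengths into random
background (default uniform base composition), and emits a truth table
derived from the construction — which the screening module must reproduce
exactly. `generate_plate()` draws Cq = intercept + slope·log10(conc) +
N(0, σ) over a dilution series (default 100 pg/µL down to 0.001 in
tenfold steps, i.e. 200 pg to 2 fg per 2-µL-template reaction, in
triplicate), with non-detects from the 40-cycle ceiling and a dropout
probability below a full-detection threshold. Defaults — slope -3.53 (92%
efficiency), intercept 36, σ = 0.15 cycles, threshold 0.1 pg/µL — emulate
a well-behaved mitochondrial assay on a tissue dilution series. All
randomness is scoped to the spec's seed (`withr::with_seed`); identical
specs give byte-identical output.

What the simulators do *not* emulate: amplification kinetics, PCR
inhibition, probe chemistry, inter-individual mtDNA:nDNA variation, and
sequence-dependent dropout. Passing tests therefore demonstrate the
*analytics* are correct, not that any wet-lab assay will behave.

## Numerical choices and problem sizes

Half-up rounding for reported percentages; strict inequalities where the
criteria say "less than"; stable, fully-keyed sort orders so reruns and
permuted inputs give identical output; errors (never silence) for
degenerate inputs — too-short templates, single-row alignments, all-ND
standards, unlabeled samples, unknown configuration keys (named in the
message).

The test suite exercises: exhaustive design-oracle equality on ~174-bp
templates, 1000-subject zero-budget screening equivalence, 1000 random
dropout patterns against a brute-force LOQ scan, and 500 seeded plates at
σ = 0.15 for slope-CI coverage (≥ 90%). These sizes keep the full suite
around two to three minutes on a single core while leaving the statistical
checks well-powered.

## Known limitations

- Hamming-only screening (no indels, no thermodynamic ΔG off-target
  model).
- Secondary structure (hairpins, primer-dimers) is out of scope — it is
  not among the selection criteria implemented.
- The Tm engine matches printed assay tables under the default conditions,
  but other software may use different parameter sets; compare within a
  tolerance, not bit-exactly.
- LOQ/LOD are properties of a standard material, not of the assay alone;
  studies must re-establish them with their own standards.
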