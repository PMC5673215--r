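---
title: "Methods: CHOS deacetylation patterns, CE4 screening and activity metrics"
author: "chosda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHOS deacetylation patterns, CE4 screening and activity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chosda)
```

# Scope and model

Chitin deacetylases (CDAs, carbohydrate esterase family 4) remove acetyl
groups from chitooligosaccharides (CHOS), oligomers of
N-acetylglucosamine (A) and glucosamine (D).  Three questions organize
this package:

1. **Which candidate proteins in a sequence collection are plausible
   secreted single-domain CE4 deacetylases?** (`runCascade` and friends)
2. **Where along a CHOS chain does a deacetylase act?** — read out by
   labeling reaction products at the reducing end with 2-aminoacridone
   (AMAC) and sequencing them by MS2 fragment ladders
   (`rankPatterns`, `positionalSupport`, `endDiagnostics`)
3. **How active is the enzyme on different substrates?** — single-point
   acetate-release assays summarized as ASAR, deacetylation degree,
   release rate and apparent rate constant (`deriveMetrics`)

A fourth component, the synthetic-data generators, produces inputs with
known ground truth for all three.

All patterns are written **non-reducing end → reducing end**, and every
report written to disk carries that convention in its header.

# Mass arithmetic

Residue and adduct masses come from elemental compositions (GlcNAc
residue C8H13NO5 = 203.0794 Da, GlcN residue C6H11NO4 = 161.0688 Da,
acetyl delta C2H2O = 42.0106 Da, AMAC C13H10N2O = 210.0793 Da,
monoisotopic).  An unlabeled oligomer weighs the residue sum plus one
water.  AMAC labeling proceeds by reductive amination: the condensation
removes the reducing-end water and the reduction adds H2, so a labeled
oligomer weighs the residue sum + AMAC + H2 — a constant +194.0844 Da
over the unlabeled species, independent of the pattern.  Only
singly-to-n-protonated positive ions are modeled ((M + z·H+)/z); no
sodium/potassium adducts, no isotope envelopes.

The default mass convention is monoisotopic: the computed protonated
ions of GlcNAc-AMAC (416.18), GlcN-AMAC (374.17) and the AMAC-labeled
mono- and di-deacetylated pentamers (1186.49, 1144.48) all fall within
0.12 of the unit-resolution ion-trap readouts they correspond to.  An
average-mass table is provided for completeness; at the default match
tolerance of **0.5 m/z** (appropriate for unit-resolution ion-trap
data acquired over m/z 150–2000) either convention matches.

# MS2 pattern ranking

Glycosidic cleavage of an AMAC-labeled CHOS gives **Y ions** (reducing
end retained, label retained: the sequence-bearing ladder) and **B
ions** (unlabeled oxocarbenium prefixes).  Only these two types are
enumerated — cross-ring cleavages and C/Z/A/X ions are not modeled
because labeled-CHOS spectra are dominated by the label-retaining
series.

`rankPatterns` enumerates all C(DP, nD) positional isomers of the
composition inferred from the precursor, and scores each by the
**explained-intensity fraction** of its ladder: the share of total MS2
intensity carried by peaks within tolerance of at least one predicted
ion.  Peak–ion matching is nearest-within-tolerance, and one peak may
support several isobaric ions — positional isomers share most fragment
masses, and exclusive assignment would silently discard evidence.
Peaks explained only by B ions enter the score with weight 0.25
(configurable): B ions corroborate but do not carry the label.  Ties
break lexicographically, making the ranking deterministic.

Two consequences are worth keeping in mind:

* the score of a *wrong* isomer is typically high (0.5–0.9), because
  shared ions explain shared intensity; what separates isomers is the
  small set of composition-distinct ladder ions;
* scores are invariant to intensity rescaling and peak order, but not
  calibrated abundances.

`positionalSupport` converts a ranking into per-position deacetylation
frequencies, f_i = Σ_p w_p · [pattern p has D at i], with weights
w_p ∝ score^γ.  The default **γ = 4** sharpens the soft weighting
enough that a decisively won ranking approaches an indicator, while a
genuine mixture (two isomers with near-equal scores) splits its support
— a reproducible, tunable version of reading mixed-isomer spectra
qualitatively.  The frequencies always sum to nD exactly.  An
**ambiguity flag** is set when the top two scores differ by less than
ε = 0.05 (absolute score), or when every score is zero (uniform f
returned); quantitative MS intensities of isomer mixtures are not
reliable, so the flag rather than the raw frequencies should gate any
strong claim.

`endDiagnostics` reads the chain termini directly: Y1 at 416.18 vs
374.17 distinguishes an acetylated from a deacetylated reducing end,
and the Y_(DP−1) composition distinguishes which residue was lost from
the non-reducing terminus (losing a D leaves an (nA, nD−1) fragment).

# The screening cascade

`runCascade` formalizes a five-filter candidate funnel:

| stage | predicate | default heuristic when unannotated |
|---|---|---|
| f0 | CE4 family tag | annotation only; unannotated proteins pass |
| f1 | all five motifs | ordered chain MT1→MT5, greedy earliest-occurrence |
| f2 | gene complete | starts with M, no internal stop |
| f3 | signal peptide | three-clause heuristic below |
| f4 | single domain | mature length ≤ 400 aa |

The five CE4 motifs are T(F/Y)DD, H(S/T)xxH, RxPY, DxxD(W/Y) and LxH
(the catalytic base/metal aspartates, metal histidines, oxyanion-hole
backbone, groove wall, and catalytic acid histidine).  "R(P/x)PY" is
read literally as R-any-P-Y and "LxH" as a 3-residue motif; both are
ordinary patterns that can be replaced wholesale via the `motifs`
argument.  Ordering along the sequence is required by default because
the CE4 fold presents the motifs in order; `ordered = FALSE` relaxes
this.  Because each motif has a fixed length, the greedy
earliest-occurrence chain is guaranteed to find an in-order,
non-overlapping assignment whenever one exists.

The signal-peptide heuristic is a transparent stand-in for a dedicated
predictor, not a reimplementation of one: (i) ≥ 1 K/R in residues 2–6,
(ii) an 8-residue window within positions 6–25 with mean
Kyte–Doolittle hydropathy ≥ 1.5, (iii) cleavage after the first
position 16–35 whose −3 and −1 residues are small (A/G/S/C/T).
External predictor calls supplied in the annotation table always
override it, as do completeness flags and domain counts — the
heuristics exist so that the cascade runs on bare FASTA.

Two design points were genuinely open and decided as follows.  The
*single-domain* proxy is a mature-length threshold of 400 aa: CE4
catalytic domains are ~200 aa, so 400 is permissive enough not to
reject a true single-domain enzyme with long termini, while catching
two-domain architectures.  *Completeness* without metadata is the
minimal auditable criterion (initial M, no internal stop); anything
subtler (truncated 3' ends and the like) requires gene-model metadata
that the annotation table can carry.  Both are configurable, and both
matter only when annotations are absent.

Every filter is a per-protein predicate, so the final candidate set is
the intersection of the per-filter sets and is invariant to filter
order; only the intermediate funnel counts depend on the order.

# Activity metrics

For a single-point assay (substrate, released acetate in µM, time,
enzyme concentration), `deriveMetrics` computes:

* **ASAR** — the substrate amount expressed as acetyl-group
  concentration: molar concentration × acetyls per molecule, or mass
  concentration / residue molar mass × fraction acetylated (reported to
  3 significant figures).  For polymeric substrates whose residue-mass
  assumptions are not available, ASAR is accepted as a direct input.
* **deacetylation degree** = 100 × acetate / ASAR (%) — volume-free;
* **release rate** = acetate (µM) × volume (ml) / time (min), nmol/min;
* **apparent rate constant** k_app = acetate / (time (s) × [enzyme]
  (µM)), s⁻¹ — a single-point turnover frequency, not a fitted
  Michaelis–Menten constant.

The default reaction volume is 0.1 ml; it is the unique volume that
makes the µM-acetate and nmol/min columns of the built-in reference
panel (`chitinDeacetylaseAssays()`) mutually consistent.  Report
formatting follows magnitude (≥ 10: one decimal; ≥ 0.01: two; else
three) because degrees span four orders of magnitude across substrates.

# Synthetic-data generators

**Deacetylation ensembles.** `simulateDeacetylation` treats each
acetylated position as an exponential clock with rate k_i; with a
neighbor penalty < 1 a Gillespie algorithm rescales each hazard by
penalty^(deacetylated neighbors), modeling the slowdown of second
deacetylations next to an existing D.  There is no explicit
enzyme-binding or subsite model: the observable the simulator must
reproduce is a positional preference, and independent-or-penalized
clocks are the simplest process with that freedom.  With penalty = 1
the closed form P_i(t) = 1 − exp(−k_i t) (`analyticOccupancy`) is
available and serves as the simulator's oracle.

The default rate profile (`rateModel`) encodes the qualitative
positional preference established for this enzyme class on the
pentamer — internal sugars most reactive, the non-reducing end an
order of magnitude slower, the reducing end slower still
(k = 1e-3, 1e-4, 2.5e-5 s⁻¹ respectively).  The *ordering* is the
modeled fact; the absolute magnitudes are conventions chosen to give
convenient half-lives (~12 min internal), because no positional rate
constants have been measured.  Conclusions that depend on magnitudes
rather than ordering cannot be supported by these defaults.

**Spectra.** `synthSpectrum` emits the Y (and 0.3-weighted B) ladders
of a same-DP pattern mixture with intensities proportional to pattern
frequency (unit response factors — a convention, since real
AMAC-CHOS response factors are unknown), Gaussian m/z jitter, and
uniform random noise peaks, all reproducible under a fixed seed.

**Protein collections.** `synthProteinCollection` builds six planted
categories (wrong family, missing motif, incomplete gene, no signal
peptide, multi-domain, positive) whose default counts
(16/24/8/11/4/1) tile a 64 → 48 → 24 → 16 → 5 → 1 funnel by
construction.  The random background excludes H, D, W and Y — the four
residues every CE4 motif depends on — so motif occurrences are exactly
the planted ones and the truth table is exact rather than
probabilistic.  Planted signal peptides are engineered so the
heuristic's first valid cleavage site is position 19.  These
constructions make the generator a *logic* fixture: it validates the
filters and the round-trip inference, not the statistics of any real
metagenome (real collections have homologous backgrounds, partial
motifs, and signal peptides the heuristic will miss — which is why
external predictor calls override it).

# What the tests do and do not show

The suite verifies: exact mass arithmetic against hand-computed values
and printed ion-trap anchors (±0.5); exhaustive ranking recovery for
all 126 patterns of DP ≤ 6 on noiseless ladders, cross-checked by an
independent differential-ladder reader; scanner equivalence with a
brute-force matcher on 1000 random sequences; simulator agreement with
the closed form within 3 Monte-Carlo s.e. at n = 10000; the
by-construction funnel; and the full round trip
simulate → spectrum → rank → positional ordering
(internal > non-reducing > reducing).  Problem sizes (10000 molecules,
100-seed jitter sweeps, DP ≤ 6 enumerations) keep the full suite
around a minute while leaving Monte-Carlo error well below the
assertion margins.

Passing these tests shows the machinery is self-consistent and agrees
with the published anchor values; it does not show that real spectra
of real reaction products will be as clean as the generator's (no
in-source fragmentation, no adducts, no co-isolated precursors), nor
that the heuristic filters reproduce a dedicated predictor's calls on
real proteins.  Quantitative isomer abundances from MS2 intensities
remain qualitative; the ambiguity flag is the honest summary of that
limit.
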