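---
title: "Identifying co-fragmented proteoform pairs in multiplexed top-down spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying co-fragmented proteoform pairs in multiplexed top-down spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In top-down DDA mass spectrometry, an isolation window of a few m/z often
captures ions of two different proteoforms. Both are co-fragmented, and the
resulting MS/MS spectrum is *heterogeneous multiplexed* (HetM): its
deconvoluted fragment masses are a mixture from two proteins, plus noise.
Conventional search engines pair only the highest-intensity precursor with
the fragment masses. That loses the second proteoform entirely, and — worse —
when the *minority* precursor happens to carry the higher isolation-window
intensity, the search frequently assigns the majority proteoform's fragments
to the wrong precursor. We call that a **precursor selection error (PSE)**:
the reported protein belongs to the *other* co-isolated precursor. An
identification matching neither precursor's protein is a **random matching
error (RME)**.

`topdemux` identifies *both* proteoforms of a two-precursor HetM spectrum and
mitigates PSEs, operating on deconvoluted neutral fragment masses.

## The method

For a spectrum with precursors $F_1$ (highest isolation-window intensity,
$I_1$) and $F_2$ ($I_2$):

1. **Multiplexed classification.** The spectrum is multiplexed iff
   $I_2 / I_1 \ge \alpha$ (default $\alpha = 0.2$, inclusive). Otherwise only
   $F_1$ is searched.
2. **Primary precursor selection.** Both precursor-fragment paired spectra
   (PFPS) — each precursor with *all* fragment masses — are searched against
   the target-decoy protein database. If only one PFPS yields a
   proteoform-spectrum match (PrSM), its precursor is primary. If both do,
   the spectrum is *error-prone* when the two PrSMs hit the same protein or
   share at least $\beta = 0.7$ (inclusive) of their matched fragment masses,
   $|M_1 \cap M_2| / \min(|M_1|, |M_2|)$. For error-prone spectra the
   precursor whose PrSM has the higher **NNMFM**
   $$\mathrm{NNMFM} = x - y\,\delta - z\,\gamma$$
   is primary, where $x$ is the matched-fragment count, $y \in \{0,1\}$ the
   number of unknown mass shifts ($\delta = 5$ per shift), and $z = 1$ for
   the second-intensity precursor ($\gamma = 4$), reflecting that
   lower-intensity precursors typically produce fewer fragments. Ties, and
   non-error-prone spectra, default to $F_1$.
3. **Two-round search-and-subtract.** The primary precursor is searched
   against all fragment masses; the matched masses of its PrSM (literal
   spectrum entries, not tolerance neighborhoods) are removed; the secondary
   precursor is searched against the remainder. If both rounds return the
   same protein, only the lower-E-value PrSM is kept.
4. **Filtering and grouping.** Round-1 and round-2 PrSMs are pooled
   separately and each pool is filtered at a spectrum-level target-decoy FDR
   (default 1%; a fixed E-value cutoff is available instead). Survivors are
   clustered into proteoform groups — single linkage under "same proteoform
   feature, or same protein and precursor mass difference `< 1.2` Da (raw
   precursor neutral masses)" — and groups are filtered at a proteoform-level
   FDR.

### The search engine

The matcher is deliberately minimal: it supports exactly the two proteoform
classes the downstream logic distinguishes — zero unknown shifts and one
unknown shift — with b/y-type fragments.

* Theoretical masses of a candidate are its neutral prefix (b-type) masses
  and the precursor-based suffix complements. A fragment mass $m$ matches a
  theoretical mass $t$ when $|m - t| \le \text{tol} \cdot t$ (default
  15 ppm, a typical Orbitrap top-down tolerance); each experimental mass
  counts at most once.
* A candidate is searched **zero-shift** when
  $|m_\text{prec} - m_\text{prot}| \le 1.2$ Da (absorbing ±1 Da isotope
  errors) and **one-shift** otherwise, with the shift fixed at
  $m_\text{prec} - m_\text{prot}$ and required to lie in $[-50, 200]$ Da.
  The shift is localized after a split site: prefixes before the split are
  unshifted, prefixes after it (and the mirrored suffixes) carry the shift;
  the matcher maximizes the matched count over all $L$ split sites
  (an $O(n \log n)$ sweep using difference arrays; an exhaustive
  enumeration serves as the oracle in the test suite). Only the shift value
  and count matter downstream, so the site itself is not reported.
* A PrSM is reported only when $x \ge 4$ matched masses (`min_match`),
  preventing one- or two-fragment coincidences from driving precursor
  selection.
* Scores are made comparable across proteins by a **binomial E-value**:
  with $n$ fragment masses in the searched spectrum and mass range $R$
  (taken as the precursor mass), a random theoretical mass hits the spectrum
  with probability $p = \min(1, 2 n \bar{\tau} / R)$, where $\bar\tau$ is
  the mean Da tolerance; the E-value is
  $N_\text{cand} \cdot P[\mathrm{Bin}(n_\text{theo}, p) \ge x]$, floored at
  $10^{-300}$. This is a calibratable surrogate, not a reimplementation of
  any specific engine's scoring: on pure-noise spectra, target and decoy
  best matches split evenly at every threshold (verified by simulation in
  the test suite). Score ties are broken by fewer shifts, lower E-value,
  then the accession *stripped of the decoy prefix*; a target tied with its
  own decoy is resolved by a deterministic hash of accession and precursor
  mass. Breaking ties by raw accession would systematically favor decoys
  (the `DECOY_` prefix sorts first) and visibly skew null calibration.

### Decoys and FDR

Decoys are per-target residue shuffles (`DECOY_` prefix, seeded,
composition- and therefore mass-preserving), giving a concatenated database
of twice the target size. The FDR estimate of an E-value-sorted prefix is
$\#\text{decoys} / \max(1, \#\text{targets})$, monotonized by a cumulative
minimum from the largest prefix (the standard q-value construction); the
largest prefix at or below the cutoff is kept, targets only. At the
proteoform level the same filter runs on group representatives (best member
E-value), with decoy groups retained up to that point so the group-level
estimate is meaningful.

## What the simulator emulates — and what it does not

`sim_params()` / `gen_benchmark()` generate random proteomes (default 50
proteins of 30–60 uniform residues) and deconvoluted spectra with:

* partial b/y coverage — each theoretical ion observed i.i.d. with
  probability `coverage` (default 0.8); real coverage is
  position-dependent, but every pipeline decision depends only on counts,
  so i.i.d. suffices;
* Gaussian relative mass error (default 5 ppm s.d.) and uniform noise
  masses (default 5 per spectrum) on $[200, 0.95 \cdot m_\text{max}]$;
* optional single mass shifts: probability 0.4 per proteoform (mirroring
  the roughly 45% one-shift share among identified non-multiplexed
  top-down spectra), value uniform on $[-50, 200]$ Da, site uniform;
* two co-isolated precursors carrying their true neutral masses, with
  $I_2/I_1$ drawn from (0.25, 0.8) so generated HetM spectra classify as
  multiplexed at the default $\alpha$.

HetM pairs are drawn from mass-adjacent proteins (heavier member gets the
higher-intensity precursor), so the cross-precursor mass difference usually
falls inside the allowed shift window — the regime where misassignment is
actually possible, as co-isolation implies for real data. Two scenarios:

* **normal** — the high-intensity precursor contributes at least as many
  fragments as the second (subsampling enforces the order);
* **swapped-intensity** — the high-intensity proteoform is observed at
  `coverage / 3` and capped at half the other's fragment count. Intensity
  rank and fragment majority then disagree, which is precisely the PSE
  setting: a naive top-intensity-first search matches the majority
  proteoform's fragments to the wrong precursor through a spurious
  one-shift alignment. The 1/3 factor was fixed a priori to leave a clear
  margin between the spurious cross-match (roughly half the majority
  fragments) and the minority proteoform's own match.

Not simulated: isotopic envelopes and deconvolution artifacts, charge-state
distributions, chromatographic elution, position-dependent fragmentation
propensity, and HomM spectra (two proteoforms of the *same* protein), which
the method does not attempt to resolve. Passing tests therefore demonstrate
the correctness of the decision logic under the stated statistical
structure, not end-to-end performance on raw instrument data.

## Pseudo-multiplexed benchmarks

Mirroring benchmark construction from real runs, `identify_nonmultiplexed()`
keeps spectra whose top precursor holds at least 85% of total precursor
intensity and identifies them single-precursor-wise. Two constructions
follow:

* **SPMS** (`pair_spms()` + `make_spms_dataset()`): all spectrum pairs with
  different precursor charges, average precursor m/z within 1.5, and
  different protein identifications; the member with more matched fragments
  is the base spectrum (ties: smaller spectrum id), merged with *all*
  additive fragments.
* **RPMS** (`pair_rpms()` + `make_rpms_datasets()`): for each base spectrum,
  the first valid zero-shift and one-shift additive spectra (charges differ,
  m/z within 20, different proteins, and — after removing additive
  fragments randomly matched to the base proteoform's b/y ions — at least
  twice the base's matched count remain). Eleven datasets with
  additive-base ratios 0%, 20%, …, 200% take exactly
  `round(ratio * n_base)` additive fragments (clamped to availability, with
  a message), drawn without replacement under one seed.

Exact duplicate masses collapse on merging (keeping the higher intensity),
since fragment lists are strictly increasing by invariant. The source
spectra for these benchmarks are generated with a per-spectrum coverage
range (0.25–0.9) rather than a fixed coverage: the RPMS validity rule
compares base and additive fragment counts, which on real data vary widely
between identified spectra.

`evaluate_errors()` scores accepted PrSMs by precursor role (rank 0 = base):
correct / PSE / RME / missed, with counts per role summing to the truth
entries. `sweep_delta_gamma()` re-runs the pipeline over a
$(\delta, \gamma)$ grid and tabulates per-role rates.

## Numerical and design choices

* All masses are neutral monoisotopic Daltons; m/z appears only in
  isolation-window bookkeeping. Standard residue masses; water
  18.010565 Da.
* The spectrum dialect prints masses with 5 decimals and intensities
  with 2, making write–read round trips exact at the printed precision and
  re-serialization byte-identical.
* "Intensity ratio exceeds $\alpha$" and "shared ratio $\ge \beta$" are both
  *inclusive* boundaries; the 1.2 Da group threshold is *exclusive*
  (strictly less). Grouping compares raw precursor neutral masses, not
  shift-adjusted ones.
* NNMFM ties select $F_1$; spectra where neither PFPS identifies also fall
  back to $F_1$, and both rounds still run (round 2 then searches the full
  fragment list, since nothing was subtracted).
* For the naive single-precursor baseline (`select_primary = FALSE,
  second_round = FALSE`) at most one PrSM per spectrum is possible by
  construction; this is the comparator used throughout.
* Degenerate inputs: empty fragment lists and empty databases flow through
  to empty result tables; zero top-precursor intensity classifies as
  single (with a message); matched counts exceeding the theoretical count
  (possible when several experimental masses fall inside one tolerance
  window) are clamped in the E-value only.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which the checked properties
are statistically unambiguous: 50-protein proteomes (plus 50 decoys);
50 spectra for exact perfect-information recovery (coverage 1, no error,
no noise); 200 spectra each for the swapped-intensity PSE comparison
(coverage 0.8, 5 noise masses) and the sensitivity comparison; 500
pure-noise spectra (60 noise masses each, `min_match = 1` so even weak null
matches are reported) for FDR calibration; about 80 source spectra for the
SPMS/RPMS constructions; and a 60-spectrum swapped-intensity benchmark for
the full $9 \times 9$ penalty sweep. On these, the full pipeline processes
roughly 30 spectra per second against the 100-entry target-decoy database.

## Known limitations

* Exactly two precursors per spectrum; additional co-isolated species are
  ignored. HomM spectra are out of scope.
* At most one unknown mass shift per proteoform; no terminal truncations,
  PTM dictionaries, c/z ions, internal fragments, or isotope-error
  enumeration beyond the 1.2 Da zero-shift absorption.
* The E-value is a binomial surrogate; absolute values are not comparable
  to other engines' E-values, though rankings and FDR behavior are
  calibrated.
* Precursor intensities are taken from the input file;
  `precursor_intensity()` exposes the isolation-window summation for
  callers that have MS1 feature peaks (the simulator uses it implicitly by
  construction), but feature detection itself is upstream of this package.
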