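---
title: "Models and methods behind polyphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphase)
```

## The problem

Autopolyploids (potato, sweetpotato, alfalfa, sugarcane, many forage
grasses and ornamentals) carry `m` copies of each chromosome, any of which
may pair with any other at meiosis.  Linkage maps for these species are
built from biparental full-sib (F1) families genotyped with SNP arrays or
sequencing, where each marker is observed only as an *allele dosage*: an
integer 0..m counting copies of one allele.  Two quantities must be
estimated jointly along an ordered set of markers:

* the **recombination fraction** `r_k` of every marker interval, and
* the **linkage phase** of both parents — which of the `m` homologs carry
  the counted allele at each marker (the parental haplotypes).

`polyphase` implements a hidden Markov model over the full offspring
genotype space for any even ploidy, an EM estimator of the recombination
fractions, and a sequential phase search that uses two-point likelihoods to
prune the (enormous) space of candidate phases before multipoint
evaluation.  Marker *ordering* is out of scope: the chain order is an
input, as produced by external grouping/ordering tools operating on the
exported pairwise recombination matrix.

## Meiotic model

The model assumes strict bivalent pairing with no preferential pairing, a
common recombination fraction across bivalents, independence between
bivalents, separation of sister chromatids, and no chromatid interference
or double reduction.  Under these assumptions:

* the number of distinct bivalent configurations (perfect matchings of the
  `m` homologs) is `w_m = (1/(m/2)!) prod_i C(2i, 2)` — 1, 3, 15, 105 for
  m = 2, 4, 6, 8;
* a two-locus gamete that inherits homolog subsets `S_k` and `S_{k+1}` has
  `l = m/2 - |S_k ∩ S_{k+1}|` recombinant bivalents, and unconditional
  probability `l! (m/2-l)! / w_m · (1-r)^{m/2-l} r^l / 2^{m/2}`;
* the gametic transition probability between ranked gamete states is
  `(1-r)^{m/2-l} r^l / C(m/2, l)`, and the offspring (genotype) transition
  is the product of the two independent parental factors.

A consequence worth spelling out: **at r = 0.5 the two loci are not
independent.**  The transition row is `2^{-m/2} / C(m/2, l)`, which is not
uniform over states, because both loci are constrained by the *same*
bivalent partition of homologs.  One-locus margins stay uniform, so dosage
segregation at a single marker is unaffected, but joint two-locus tables at
r = 0.5 differ slightly from the product of their margins.  The test suite
asserts the model's actual behavior rather than the (intuitive but wrong)
independence claim.

## States, emissions, priors

Gamete states are the `C(m, m/2)` half-size homolog subsets, ranked
lexicographically; genotype states are ordered pairs of parental gamete
ranks, `g_m = C(m, m/2)^2` in total (36, 400, 4900 for m = 4, 6, 8).  A
marker's phase assigns the counted allele to homolog subsets `phiP`,
`phiQ` with sizes equal to the parental dosages; a genotype state then
implies the offspring dosage `delta = |phiP ∩ S_P| + |phiQ ∩ S_Q|`, the two
parental contributions counted separately (the only reading under which
offspring dosages span 0..m).

Emissions connect `delta` to the observation.  Three options, in order of
preference:

* genotype-caller posteriors over the m+1 dosage classes, when available
  (an `(m+1) x markers x individuals` array attached to the dataset);
* hard dosage calls, optionally smoothed by a global error rate
  `epsilon` (probability `1 - epsilon` on the called class, `epsilon/m`
  elsewhere); the default is `epsilon = 0`, with 5% a documented choice
  for noisy array data;
* for missing observations, the polysomic segregation prior: each parent
  transmits a hypergeometric number of allele copies, and the offspring
  dosage distribution is the convolution of the two.

## Multipoint estimation

The chain likelihood is computed by the scaled forward algorithm over the
`g_m` states with a uniform initial distribution.  Because the transition
factorizes over parents, all propagation uses `C(m,m/2) x C(m,m/2)` matrix
products (a Kronecker identity), never `g_m x g_m` matrices; the same
factorization evaluates the EM update — each `r_k` is replaced by the
posterior expected proportion of recombinant bivalents
`E[(l_P + l_Q)/m]`, averaged over individuals — in three batched matrix
products per interval.  Numerical behavior: per-marker scaling constants
(the forward-backward identity `sum_j alpha beta = 1` is asserted in
tests); estimates are clamped to `[1e-7, 0.5]` to avoid log singularities;
EM defaults are tol `1e-4` on `max |Δr|`, at most 1000 sweeps, initial
`r = 0.01` per interval (a map-scale prior; the estimator is insensitive to
it).  EM near a flat likelihood converges slowly, so equivalence tests
(two-point vs multipoint) run both to tight tolerance.

## Two-point engine

For a marker pair the genotype space collapses onto the `(m+1)^2` joint
dosage table `A(r)`.  The parental halves are independent, so `A(r)` is
built as a 2-D convolution of two per-parent gamete-dosage tables whose
polynomial coefficients (counts of gamete-state pairs by dosage
contribution and recombinant count) are computed once per
`(m, dosages, sharing value)` and cached.  The linkage phase of a pair
reduces, per parent, to the *sharing value* `w`: the number of homologs
carrying the allele at both loci.  All subset pairs with the same `w`
yield identical tables (verified against explicit representatives), so one
canonical representative per partition is used.  Estimation is EM on the
collapsed table (expected recombinant proportion per dosage cell; start
0.25, tol `1e-6`, max 200 iterations); LOD scores are reported against
r = 0.5 (linkage) and against the best partition (phase).  Pairs whose
table does not depend on `r` are flagged uninformative with `r = 0.5`.
Fisher information for any pair/phase is available in closed form from the
polynomial coefficients, reproducing the qualitative ordering that coupled
single-dose pairs are more informative at small `r` than repulsed ones.

## Sequential phase search

Markers are inserted in chain order.  For a new marker, each parent's
candidate subsets are screened by two-point LOD profiles against a window
of terminal phased markers (threshold `eta`); surviving assignments are
crossed between parents and deduplicated up to homolog permutation by a
canonical row-sorted form of the binary homolog-by-marker matrix.  The
expansions are scored by the multipoint likelihood after a short EM
refresh (5 sweeps, the new interval initialized at r = 0.01; the full EM
is reserved for the final refit; the short refresh is a deliberate
approximation trading a negligible likelihood bias during screening for a
large speedup), and candidates within `multipoint_lod` of the best are
retained.  Defaults: `eta = 5` (a conservative screen -- a higher threshold passes
more candidates on to multipoint evaluation, trading speed for robustness
to weakly informative marker pairs), `multipoint_lod = 10`, `window = 50`.
The replicated studies in the acceptance suite use `eta = 3`, matching the
small-scale design they scale down.  A marker for which no assignment survives is
skipped and reported rather than aborting; the multipoint LOD threshold is
applied after the new marker's EM refresh.  With pruning disabled the
search provably returns the exhaustive maximum-likelihood phase on small
instances (tested at m = 4, z = 3).

## Simulator: the stated world

The generator draws, per offspring and parent, a bivalent configuration
(uniform over the `w_m` matchings) and switches each bivalent's
transmitted homolog across interval k with probability `r_k`,
independently across bivalents — exactly the process the HMM assumes: no
crossover interference, no obligate chiasma, no multivalents, no double
reduction.  Parental haplotypes follow three placement scenarios of
increasing difficulty: A (alleles on the leading homologs), B (contiguous
block starting in the first m/2 rows), C (uniformly random subsets).
Marker dosages default to uniform on `1..m-1` — every marker informative
in both parents, a deliberate choice where the source design left the
dosage distribution unstated; it matches the common practice of filtering
monomorphic markers before mapping.  The replicated studies use n = 200 offspring and 10 markers at 1 cM.

Preferential pairing is available for robustness studies only, as a
mixture: with probability `p` the fixed partner matching
(1,2)(3,4)(5,6)..., else a uniform matching.  This is a simplification of
specialized meiosis simulators (which model pairing-partner switch
positions and quadrivalent geometry); multivalents and double reduction
are not simulated at all.  Consequently chromosome-scale robustness
benchmarks built on specialized meiosis simulators are only qualitatively
approachable here: the acceptance suite asserts the *direction* (recovery
degrades at `p = 0.5` for hexaploids with `eta = 3`), not any particular
percentage.  Under this
mixture the degradation materializes mostly through the two-point screen
rejecting the true phase as the chain grows (the affected marker is
skipped), so the smoke test needs a chain long enough for rejections to
accumulate: at 6 markers both pairing levels still recover every
replicate, at 8 markers the biased level visibly fails — hence the 8-marker
design.

What a green replicated study does establish: under the model's own
assumptions the sequential search recovers the exact parental haplotypes
(up to homolog permutation — the only identifiable representation) in 100%
of scenario-A replicates at m = 4 and m = 6, with median RMS map-distance
error at most 1 cM (the acceptance suite computes and asserts both).  What it does not establish: performance under
segregation distortion, multivalent meiosis, missing-data patterns of real
assays, or mis-specified marker order.

## Numerical and design notes

* All enumerations (subsets, matchings, sharing values) have fixed,
  documented orders; ties in likelihood are broken by enumeration order,
  lowest sharing values first, so runs are bit-reproducible given a seed.
* Candidate scoring treats an individual whose data are impossible under a
  candidate phase (at `epsilon = 0`) as likelihood zero for that candidate
  (`-Inf` log-likelihood) rather than an error; fitting the *final* chain
  with contradictory data is an error naming the individual and marker.
  Observations outside the feasible polysomic dosage classes should be
  filtered to missing first (`filter_impossible_dosages`), the standard
  pre-mapping rule.
* A master seed spawns per-replicate substreams in studies, so any
  replicate can be reproduced in isolation.
* Enumerating bivalent configurations is capped at m = 8 by default (the
  count grows as (m-1)!!); the probability model itself uses closed forms
  and has no such cap.

## Limitations

Ordering is not estimated; quadrivalent/multivalent pairing and double
reduction are excluded from both model and simulator; the preferential
pairing robustness check is a simplified mixture; the VCF reader is a
minimal convenience for uncompressed files with GT or DS fields, not a
general VCF implementation; and two-point screens lose power for
multi-dose markers in repulsion at large distances (their Fisher
information profiles can be inspected with `fisher_information`).
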