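---
title: "Mapping noisy long reads by successive refinement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping noisy long reads by successive refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchoralign)
```

This vignette is the package's own account of its models and of the
choices made where the design was genuinely open.  Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The error model and why anchoring works

Single-molecule reads err independently per base at a rate $\rho$ of
10–20%, dominated by insertions and deletions.  Under independence, the
lengths $W$ of error-free runs are geometric:
$\Pr\{W \ge K\} = (1-\rho)^K$, with mean run length $1/\rho - 1$ — about
5.67 bases at $\rho = 0.15$.  An *average* run is therefore useless as a
seed (any 5-mer is everywhere in a genome), but the *distribution* has a
heavy enough tail that long runs appear regularly.  `waiting_length()`
quantifies this: the number of error-free words $t$ that must be
sequenced before one of length $\ge K$ appears with probability
$1-\varepsilon$ is $t = \log\varepsilon / \log(1 - (1-\rho)^K)$, and the
corresponding expected number of bases is
$t\,(1/\rho - K(1-\rho)^K/(1-(1-\rho)^K))$.  At $\rho = 0.15$,
$K = 15$, $\varepsilon = 0.05$ this is about 33 words or 171 bases — so a
kilobase read is all but guaranteed several seeding anchors.

### Exact composition counts

Fixing the number of errors $M$ in a read of length $L$, the error
positions cut the read into $M+1$ parts forming a strict composition of
$L+1$; parts exceeding $K$ are anchors.  `compositions_poly()` extracts
the coefficient of $t^{L+1}$ in
$\binom{M+1}{N} A(t)^N S(t)^{M+1-N}$ with $S(t) = t(1-t^K)/(1-t)$ and
$A(t) = t^{K+1}/(1-t)$, truncating every intermediate at degree $L+1$.
All intermediates are nonnegative and bounded by the result, so exact
doubles suffice whenever $\binom{L}{M} < 2^{53}$ (the function refuses
larger inputs).  `compositions_closed()` evaluates the alternating closed
form
$\binom{M+1}{N}\sum_i (-1)^i \binom{M+1-N}{i}\binom{M+D-iK}{M}$,
$D = L-NK-M$, in exact big-integer arithmetic: at $M=75$, $N=1$,
$K=15$, $L=1000$ the 61 nonzero terms span magnitudes $2^{93}$ to
$2^{401}$ while the sum is only $2^{294}$, so every fixed-precision
evaluation loses all significant digits.  No arbitrary-precision integer
package is declared; the package carries a small exact integer layer
(base-$2^{15}$ limb vectors, `bn()` and friends) providing exactly the
operations the counts need, which keeps the computation dependency-free
and auditable.

Two values printed in discussions of this model deserve a note.  First,
the magnitudes above are *bit lengths* (`bn_bits()`, i.e.
$\lfloor\log_2 x\rfloor + 1$).  Second, exact computation gives
$\Pr\{N \ge 10\} = 0.9388$ for $L=1000$, $M=150$, $K=15$
(`num_configurations(150, 10, 15, 1000)`), a little below the
often-quoted "97%" for those parameters; the package reports the exact
number.

For $K = 0$ every part is an anchor, so the count is $\binom{L}{M}$ when
$N = M+1$ and zero otherwise (the degenerate branch follows the
derivation, not a binomial in $N$).  The moments of $N$
(`composition_moments()`) are
$\mu = (M{+}1)\binom{L-K}{M}/\binom{L}{M}$ and
$\sigma^2 = M(M{+}1)\binom{L-2K}{M}/\binom{L}{M} + \mu - \mu^2$, and for
large $M$ the pmf is close to $\varphi((N-\mu)/\sigma)/\sigma$ with
survival $1 - \Phi((N - \tfrac12 - \mu)/\sigma)$
(`normal_approx()`; the $1/\sigma$ normalisation is required for the
density to integrate to one — the acceptance tests verify agreement with
the exact pmf to within 0.01 at $L=1000$, $M=150$).

## The mapper

### Anchoring

The suffix array (prefix doubling, Rcpp) answers `COUNTLCP` by
binary-search interval narrowing, one character depth at a time, keeping
the interval at every depth so the anchor scan can re-read the count at
the shortened emission length.  Emitting matches one base shorter than
the LCP (`lcp_shorten = 1`) avoids anchoring *through* a base-call error
that happens to extend a match; the floor is `K = 12`.  `max_count =
10000` bounds the per-position hit list in repetitive genomes.  N bases
are indexed but any anchor containing one is rejected, which prevents
poly-N matches from seeding clusters.  Concatenated references are
separated by a sentinel byte, so no query can match across a boundary.
Both strands are scanned independently (the read and its reverse
complement against the forward genome) and clusters never mix strands.

### Clustering and the frequency-weighted score

Within every window of anchors whose genome extent fits a read length,
the maximal chain is found under the objective *total anchor bases* (not
anchor count), because anchor bases are also the downstream significance
statistic; ties break toward larger anchor bases, then the leftmost
genome start.  Windows whose membership is a subset of an already-chained
window are skipped, and contained or duplicate chains are removed —
without this, every anchor of a dense cluster would spawn its own nearly
identical chain and inflate the candidate ranks.

Clusters are ranked by the frequency-weighted score
$\sum_a \log(1/\mathrm{Freq}(a))$.  Read literally with raw occurrence
counts, every term is $\le 0$, so a dense 30-anchor cluster containing a
single repeated anchor would rank *below* a spurious two-anchor cluster
of unique matches — we measured exactly this failure (mapping accuracy
collapsed to ~60% on a 1 Mb simulation).  The score is only
discriminative when frequency means *relative* frequency, i.e.
$\sum_a \log(G/\mathrm{count}(a))$, under which each anchor contributes
positively and repetitive anchors contribute less.  `rank_clusters()`
therefore adds the $n\log G$ normalisation whenever the genome length is
supplied (the mapper always supplies it); without `G` it reproduces the
raw-count ordering, which remains available for didactic use.

### Candidate intervals, SDP, and the guide band

A cluster's interval extends the chained span by $(1+\delta)$ times the
unanchored read flanks, $\delta = 0.15$ being the maximum insertion rate;
fractional endpoints round outward (never excluding a true alignment
column) and clamp to the reference.  The interval end is anchored at the
*end* of the last anchor, $\mathrm{Genome}(a^{\mathrm{LAST}}) +
l(a^{\mathrm{LAST}})$, so the interval always covers the chained span.

Sparse dynamic programming chains exact `k_sdp = 11`-mers — the upper end
of the sensible 8–11 range, chosen to bound match multiplicity inside a
~1.15 kb interval — by patience longest-increasing-subsequence in
$O(n\log n)$, maximising match *count* (ties broken toward small
diagonal drift, which keeps the subsequent band tight).

The banded alignment admits, for rows covered by a chain match, a band
of half-width `b_sdp = 15` about the match's diagonal; between
consecutive matches the half-width grows to the inter-match diagonal
drift plus `b_sdp`; flanking rows extend the nearest diagonal.  The
band is then minimally widened to be monotone with overlapping
consecutive rows, which guarantees connectivity.  `b_sdp = 15` covers
the indel drift expected across one SDP gap at $\delta = 0.15$ with
margin.  If a band still excludes every complete path, the aligner
widens once to the full rectangle, then the caller demotes the
candidate.

### Alignment scoring

With quality tracks, a diagonal move costs 0 on a match, the
substitution quality $S_i$ when the alternative substitution call equals
the genome base, and MISMATCHPRIOR = 20 otherwise; a vertical move (read
insertion) costs $I_i$; a horizontal move costs $D_i$ when the
alternative deleted call equals the *preceding* interval base and
DELETIONPRIOR = 15 otherwise.  The deletion qualities are indexed by the
read row exactly as the recurrence is written, although a deletion
consumes no read base; whether the preceding read base was intended is
unknowable from the recurrence alone, and we keep the printed indexing.
Without tracks, flat penalties (20/15/15) substitute.  The alignment is
global in the read and free at both interval ends — the $(1+\delta)$
flanks exist precisely so the true alignment can start inside the
interval, and charging them would bias costs.  Traceback tie-breaking is
diagonal, then deletion, then insertion, making output deterministic.

### Mapping quality

$\Pr(r\mid g)$ is approximated by $10^{-\mathrm{cost}/10}$ — the Viterbi
(best-path) approximation to the forward probability; since costs are
already phred-scaled this is a single exponentiation, and the forward
pass would add an order of magnitude of work for a quantity that is then
dominated by its best path anyway.  The posterior of the best candidate
is taken over the at most `max_candidates = 10` aligned candidates.
Before the sum, candidates whose genome intervals overlap by more than
half are collapsed to their cheapest representative: overlapping windows
around one locus would otherwise enter the denominator repeatedly and
push Q down for uniquely-mapping reads.  When the number of *significant*
clusters (anchor bases above $\mu - 2\sigma$ under the composition
model, with the best alignment's accuracy as the read-accuracy proxy)
exceeds `max_candidates`, the denominator is scaled by their ratio —
acknowledging that the true locus may hide among the unaligned clusters
of a repeat.  Q is capped at 254 (255 is reserved in SAM for
"unavailable").

The anchor-bases moments are genome-independent, so they are precomputed
per (read-length, accuracy, $K$) bin: the mean exactly from the marginal
part-size distribution, the variance by $10^4$ seeded Monte Carlo draws
of uniform compositions.  A full grid (accuracies 0.60–1.00 by
0.01, log-spaced lengths) is available through
`anchor_bases_moments()`; the mapper itself fills bins lazily (lengths
binned to powers of two, accuracies to 0.01) so a run only pays for the
bins its reads touch.

## The read simulator

`simulate_reads()` scans a template: each position errs with probability
$\rho$, the type drawn from the mix (default 10% substitution, 62%
insertion, 28% deletion); insertions emit a uniformly random base
without consuming template, deletions consume silently, substitutions
emit a different base.  This induces the geometric run-length law the
feasibility theory assumes, and the suite checks the empirical run-length
regression slope and the event mix against the configuration.  Flat
quality tracks consistent with $\rho$ and the mix are attached, with
uniformly random alternative calls.

What the simulator does *not* emulate: homopolymer-biased insertion
composition, position-dependent error rates, the exponential read-length
distribution of real instruments, and structural variation.  Passing the
end-to-end tests therefore demonstrates correctness of the machinery
under the i.i.d. error model, not performance on any particular
instrument's reads.  A random genome also lacks the repeat structure of
real genomes; the mapping-accuracy condition on a 1 Mb random genome is
informative about sensitivity (are enough anchors found and chained?)
but not about repeat resolution, which is exactly why the mapping
quality machinery (significance scaling) exists.

## Problem sizes and numerical choices

The test suite runs its calibration at desk scale, chosen as the
smallest sizes at which the claims are meaningful rather than as
instrument-scale reproductions: a 1 Mb genome with 500 kilobase reads at
$\rho = 0.15$ for mapping accuracy (criterion: ≥95% within 50 bases,
strand-correct — 50 bases being a generous tolerance against a
kilobase read) and for the bimodality and calibration of Q; oracle
equivalence of the three counting routes over all $L \le 14$,
$M \le 5$, $K \le 4$; alignment against a full-grid oracle on 500 random
pairs up to 80 bases.  Fixed seeds (42 for the genome, 7 for the reads)
make the runs reproducible; they were set once with the study design.

Degenerate inputs are defined rather than accidental: empty anchor sets
produce empty cluster lists; an empty SDP chain falls back to a full
band; reads shorter than $K$ are reported unmapped after a logged skip;
$\rho \in \{0, 1\}$ is rejected by `waiting_length()`; zero-variance
moment bins yield a point-mass "approximation".  `compositions_poly()`
guards its exact-double precondition explicitly.

## Known limitations

* The mapper reports one best location per read; split/chimeric
  alignments and overlapping sub-read hits are out of scope.
* No affine gap model: each inserted or deleted base is charged
  independently, which is the standard choice when indels are short and
  dense, but underfits long structural gaps.
* The big-integer layer implements only what the counts need (no
  division by big divisors, no negatives outside the signed
  accumulator); it is not a general bignum library.
* BAM/CRAM output and instrument-native HDF5 input are not provided;
  SAM text is the interchange format.
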