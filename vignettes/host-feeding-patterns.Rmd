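---
title: "Methods: host-feeding patterns, null models and transmission risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-feeding patterns, null models and transmission risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostfeedr)
```

# The data model

The unit of observation is one engorged (blood-fed) female mosquito whose
blood-meal host was identified to species: a record carries the mosquito
taxon, the host species, the trapping site, the collection date, the trap
method and the site's land-use class. Host species collapse into three
host-feeding groups — birds, non-human mammals, humans — through an explicit
taxonomy table; a species absent from the taxonomy is an error, never a
silent default, because host-name typos would otherwise flow unnoticed into
every downstream statistic. Records with `"unidentified"` hosts are stored
but excluded from all tabulations.

Two derived stratifiers matter analytically. The **sampling period** splits
the year into early (January–June) and late (July–December) halves; only the
month is used. The **land-use class** of a site is the dominant of three
aggregate Corine land-cover proportions in the site's surrounding buffer
(artificial 111–142 → urban, agricultural 211–244 → rural,
forest/semi-natural/wetland/water 311–423 → natural). The package consumes
precomputed proportions; it does no GIS. An exact tie in the proportions is
refused by default — a tie means the buffer genuinely has no dominant
cover — with an explicit urban > rural > natural fallback for callers that
need a forced decision.

## The packaged survey and its reconstruction

The package ships the published count tables of a nationwide German survey
(775 blood-fed specimens, 24 mosquito taxa of which 20 are named species, 32
host species) as plain-text fixtures. `reconstruct_survey()` expands them
into a record-level dataset whose *margins* reproduce every published count
and one-decimal percentage: per-taxon host-group counts, per-host-species
totals, and the period splits of the three dominant taxa. The within-group
assignment of host species to mosquito taxa is *not* published (it exists
only as a figure), so the reconstruction fills it with a deterministic
north-west-corner transportation allocation. This is adequate for every
margin-based statistic and clearly inadequate for taxon × host-species
co-occurrence; the reconstruction is documented as synthetic in that
respect, and the per-taxon host-species richness column of the published
table is consequently not reproduced. Percentages are kept at full precision
internally and rounded half-up to one decimal only for display, matching the
published style.

# C-score null models

Host-feeding structure is tested on binary presence–absence matrices: rows
are host species, columns are mosquito taxa (survey-wide analysis) or
trapping sites (per-taxon analyses). Rows-as-hosts is a deliberate,
recorded orientation choice — the C-score is not orientation-symmetric —
following the host-feeding null-model framework this analysis descends
from. All-zero rows and columns are dropped; a matrix smaller than 2×2
after dropping is an error, not a silent pass.

For rows *i*, *j* with totals *r~i~*, *r~j~* sharing *S~ij~* columns, the
pair contributes (*r~i~* − *S~ij~*)(*r~j~* − *S~ij~*) checkerboard units;
the C-score is the mean over all unordered pairs. Low scores mean shared
columns (aggregation around common hosts), high scores mutual exclusion
(segregation).

The null holds each row's total fixed and re-places its 1s uniformly at
random over the columns, rows independent — the fixed-equiprobable
algorithm. Defaults: 5000 randomizations and a *required* explicit seed
(there is no wall-clock fallback, so every result is reproducible by
construction). Tail probabilities use the add-one convention,
p = (#{null ≤ observed} + 1)/(n + 1), so p ∈ (0, 1] and the smallest
reportable p at n = 5000 is ≈ 2·10^−4^; ties (within 10^−9^, since C-scores
are rationals with denominator "number of row pairs") count toward both
tails, which is conservative. The verdict is aggregated if the lower tail
is below α = 0.05, segregated if the upper tail is, random otherwise.

Correctness rests on two independent oracles in the test suite: exhaustive
enumeration of the fixed-equiprobable outcome space on small matrices
(every 3×3 matrix with row sums ≤ 2, canonicalized up to row order, which
the statistic provably ignores and a property test confirms), and
calibration on generated scenarios — aggregated matrices built around a
universal host column plus one uniformly placed extra 1 per row, segregated
matrices partitioning the columns, and random matrices drawn from the null
itself (6 hosts × 10 columns). The null-model verdict must recover the
generator's kind with high power on the structured scenarios and near-nominal
false-positive rate on the random ones; the acceptance script recomputes
both rates (100 replicates × 5000 randomizations).

The published survey-wide C-score values themselves are **not**
reproducible: they require the specimen-level host × taxon matrix, which was
never published. The package therefore validates the machinery, not those
numbers.

# Frequency comparisons

Period comparisons build the period × host-group table per taxon and apply
Pearson's chi-square with expected counts from the marginals. Two numerical
conventions are forced by the published worked examples and are therefore
fixed: host groups with zero marginal totals are dropped *before* testing
(so a taxon never observed on birds is tested on a 2×2 table with df = 1),
and Yates' continuity correction is applied exactly when the reduced table
is 2×2. Expected counts below 5 raise a warning flag on the result but are
never fatal — the published analysis evidently proceeded through the same
warning, and refusing to compute would silently change the science.

Land-use comparisons use the tie-corrected Kruskal–Wallis H with the
chi-square approximation at every sample size (exact small-sample tables
are out of scope; group sizes below 5 are flagged). When all observations
are identical the tie-correction denominator vanishes; the statistic is
reported as 0 with a complete-ties warning rather than NaN.

Trap-method comparisons test every unordered pair of trapping methods on a
2×2 bird vs non-human-mammal table and adjust p-values over the family of
pairs. Benjamini–Hochberg is the default adjustment, with Holm and
Bonferroni selectable — the choice is open because the original analysis
names no method; BH is the conventional default for screening-style
post-hoc families.

# Host-feeding groups

Each taxon's profile is the binary triple over host groups (any count ≥ 1
sets the bit; "normalized presence–absence" means exactly this — no
abundance weighting). Dissimilarity is Jaccard, 1 − |A∩B|/|A∪B| over set
bits, a proper metric on non-degenerate triples (the suite checks all 7×7
profile pairs exhaustively). Clustering is UPGMA: merge the closest pair
under unweighted average linkage. Ties are frequent with only seven possible
profiles, so the tie-break is fixed: the pair whose sorted cluster-label
pair is lexicographically smallest merges first, making the tree a pure
function of the profile set (an input-order-invariance property test
confirms it). The implementation is authored here precisely for that
deterministic tie-break; its merge heights are cross-checked against
`stats::hclust(method = "average")` and the Jaccard matrix against vegan's
binary Jaccard in the suite.

The host-feeding *groups* are the zero-height clusters — equivalently the
equivalence classes of identical profiles, since Jaccard distance is zero
iff profiles coincide. The package reports whatever combinations are
present; it does not force any particular group count. On the packaged
survey counts this yields seven combinations: the two large groups
(non-human mammals + humans, 9 taxa; all three groups, 6 taxa), four
single-group combinations from rarely collected taxa, and two two-group
combinations ({bird, mammal} and {bird, human}) that fall out of the
published per-taxon counts. Dendrograms export to Newick via ape; labels
containing Newick-unsafe characters (parentheses, slashes) are sanitized by
the writer.

# Transmission-risk index

For taxon *t* with blood-meal fractions Fa (avian), Fm (non-human mammal),
Fh (human) and relative abundance Ap ∈ [0, 1]:

* risk(bird → human) = Ap · Fa · Fh
* risk(mammal → human) = Ap · Fm · Fh

Vector competence is deliberately not a factor — competence estimates
rarely transfer between mosquito populations, so the index measures
host-contact potential only and must be read as such. Ap is a fraction;
percentage inputs are divided by 100 at read time and the reader rejects
values outside [0, 1] after scaling. Abundance surveys often cannot
separate sibling taxa (e.g. the *Culex pipiens* complex); an explicit
`shared_with` column assigns an aggregate's abundance unchanged to each
member taxon, and the sharing is carried into the output rather than
hidden. Rankings are per channel, descending, ties alphabetical; they are
invariant to rescaling all abundances by a positive constant, so only
relative abundance matters.

# In-silico host identification

The wet-lab stage — PCR of a mitochondrial cytochrome-*b* fragment and
sequence comparison — is mirrored computationally. Primer search scans both
strands of a template under IUPAC-aware comparison in which degeneracy
lives on the *primer* side only (R matches A or G; N matches anything;
template bases are literal), with ≤ 2 mismatches per primer by default —
a permissive but standard in-silico PCR tolerance. Coordinates are 0-based
half-open on the top strand. Matching is delegated to Biostrings'
degenerate pattern matcher and verified against a naive all-offsets scan
oracle on random templates. Amplicon extraction pairs a forward site with a
downstream reverse site in amplifying orientation on either strand, returns
the primer-to-primer inclusive product read 5′→3′ from the forward primer,
and picks the shortest product when several compete (as PCR itself strongly
does); a missing site yields no product, which is a value, not an error.
The two standard vertebrate cytochrome-b pairs are built in: a ~244 bp
fragment (22 + 200 + 22 for a 200 nt insert) tried first and a ~358 bp
fragment as fallback.

Assignment aligns the query globally against every panel sequence (match
+1, mismatch 0, linear gap −1 — for equal-length ungapped pairs identity
reduces to 1 − Hamming/length, which the suite verifies) and takes identity
as the fraction of identical aligned columns. Thresholds: `min_identity`
0.95 and `min_margin` 0.02 to the runner-up. These are package defaults
chosen to separate references ≥ 10 % divergent under ≤ 2 % query noise with
a wide margin — the original sequence-comparison workflow specifies no
thresholds, so these are explicitly this package's choice and both are
arguments. Ambiguity (margin below threshold, including exact ties) is a
distinct status from unassigned (no hit at threshold). The two-tier runner
touches the tier-2 panel only for queries unassigned at tier 1, mirroring
the fallback PCR, and records the tier per call.

# The synthetic survey generator

The generator encodes the availability hypothesis structurally: each
record's host is drawn from preference × availability × trap-bias weights
(elementwise, renormalized), so uniform preferences yield purely
availability-driven feeding — the relevant null for testing whether the
analysis can tell structured host choice from community composition.
Defaults emulate the packaged survey's design: 52 sites (11 urban, 36
rural, 5 natural), the three dominant taxa with abundance weights in their
observed ratio 363:100:99, a 12-species host community (6 mammal species
including humans, 6 birds) with a mammal-dominated availability profile, a
summer-peaked seasonal curve, the observed trap-method mix, and no trap
bias. Trap bias is a per-host-group multiplicative factor per method (the
mechanism behind the familiar gravid-trap enrichment for bird feeders);
setting one reproduces such enrichment in the generated data. A
configuration in which some taxon has zero total host weight at some site
is rejected up front, naming the taxon and site.

Every generator (survey, scenario matrices, mutated amplicon sets,
synthetic reference panel) is a pure function of its configuration and an
explicit seed. The synthetic reference panel builds amplifiable references
— primer footprints flanking species-specific random inserts — whose
pairwise divergence far exceeds the 10 % the assignment defaults assume
(i.i.d. inserts are ~75 % divergent; the suite asserts ≥ 10 %).

What the generator does *not* emulate: spatial autocorrelation between
sites, host community turnover within a season, mosquito movement,
multi-host (mixed) blood meals, and digestion-related identification
failure. Passing tests therefore show that the analysis chain recovers the
generating structure under clean sampling assumptions — not that field data
meet those assumptions.

# Problem sizes and numerical conventions

The test suite and acceptance script use deliberately moderate sizes chosen
to make Monte-Carlo error negligible relative to the tolerances being
checked: the exhaustive null-model sweep runs 20 000 randomizations per
canonical 3×3 matrix against exact enumeration (tolerance ±0.02);
calibration uses 100 replicates per scenario kind at 5000 randomizations;
parameter recovery uses ~1000 records per taxon (binomial SE ≈ 0.016, so
the ±0.05 check has headroom); host-identification accuracy uses 300
queries at 2 % substitution. Floating-point ties in the null model are
resolved with an absolute 10^−9^ guard; UPGMA tie comparisons use 10^−12^.
Degenerate inputs follow one rule throughout: silently dropping data is
allowed only where the statistic defines it (zero margins, all-zero
rows/columns), and anything that would change the question being asked —
empty datasets, sub-2×2 tables, unknown species, out-of-range proportions —
is an error.

# Known limitations

* The reconstruction's taxon × host-species allocation is synthetic;
  anything beyond the published margins (notably per-taxon host richness
  and host-species-level co-occurrence) must not be read from it.
* The published survey-wide C-score values cannot be checked without the
  unpublished specimen-level matrix; validation is property-based.
* Identity thresholds for host assignment are package defaults, not
  community standards; real cytochrome-b panels with congeneric species
  closer than ~5 % divergence will need stricter margins or longer
  fragments.
* The risk index omits vector competence by design and is a contact-based
  screen, not an epidemiological model (no R0, no seasonality of
  transmission).
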