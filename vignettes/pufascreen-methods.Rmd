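---
title: "Methods: screening assemblies for rotifer LC-PUFA biosynthesis genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening assemblies for rotifer LC-PUFA biosynthesis genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Freshwater gammarid amphipods frequently carry bdelloid rotifers as
epibionts on their exoskeleton. When transcriptomes are assembled from
whole wild-caught individuals, rotifer RNA co-assembles with host RNA, and
genes that the host does not possess — notably the long-chain
polyunsaturated fatty acid (LC-PUFA) biosynthesis enzymes of the rotifers —
appear in the "gammarid" assembly. `pufascreen` packages the computational
side of diagnosing this situation: classifying candidate desaturase and
elongase open reading frames by diagnostic motifs, calling rotifer genetic
contamination from the cox1 mitochondrial barcode, comparing homologous
gene sets by nucleotide identity, analysing exon–intron organization of the
genes in a genomic context (including introner-like elements, a signature
relevant to horizontal gene transfer), and reasoning about which fatty
acids a given enzyme complement can and cannot produce.

## The reaction-network model

Fatty acids are written in the standard shorthand `C:Dn-W` (carbons,
double bonds, omega class). The model's core assumption is that every acid
in the network is **even-chain and methylene-interrupted**: double bonds
are anchored at the omega position `C − W` (counting Δ positions from the
carboxyl terminus) and spaced exactly three carbons apart. Under this
assumption the full Δ-position list is a function of `(C, D, W)`:
`Δ_k = (C − W) − 3k` for `k = 0..D−1`. The canonical representation stores
only the triple and always derives positions, which makes inconsistent
states unrepresentable. Stereochemistry, odd chains and
non-methylene-interrupted acids are out of scope.

Four operator families act on acids:

* **Front-end desaturation (Fed, Δy ≥ 4)** inserts a bond between the
  proximal existing bond and the carboxyl terminus. The precondition is a
  bond at `Δy + 3` and none at `Δy` — the strictest reading that keeps
  every product methylene-interrupted. A looser "any bond distal of Δy"
  rule was rejected for that reason.
* **Methyl-end desaturation (ωx)** inserts a bond distal to the current
  distal-most bond; the substrate's distal bond must sit at `Δy − 3` and
  the product omega class (`C − Δy`) must be 3 or 6. A Δ17-style activity
  on C20 substrates is expressible with the same operator but is not part
  of the default characterized preset, because the characterized rotifer
  enzymes show only the dual Δ12/Δ15 regioselectivity.
* **Elongation (Elovl)** adds two carbons at the carboxyl end, shifting
  every Δ position by +2; an activity carries an explicit set of
  admissible substrate chain lengths.
* **Beta-oxidative shortening** (the partial step of the Sprecher route)
  removes two carbons; it requires the proximal bond at Δ ≥ 6 so the
  product remains a valid front-end acid.

`reachable_set()` computes the breadth-first closure of precursors under
an activity set, bounded by `max_carbons = 24` (the C24 intermediates of
the Sprecher route are the longest acids the model ever needs). Frontier
nodes are expanded in lexicographic `(carbons, double_bonds, omega)` order
and each acid keeps its first discovered predecessor, so reachability and
reconstructed reaction paths are deterministic.

The shipped preset `bdelloid_characterized` — ωx Δ12, ωx Δ15, Fed Δ6,
Fed Δ5, elongation of C18 and C20 — encodes the activities demonstrated
for the rotifer enzymes in yeast. From oleic acid (18:1n-9) this set
reaches EPA (20:5n-3) and ARA (20:4n-6) but not DHA (22:6n-3); DHA becomes
reachable either by adding a Δ4 front-end activity (which needs the C20
elongation step to supply 22:5n-3) or by adding C22 elongation plus Δ6
plus shortening (the Sprecher route). The acceptance suite asserts all
three statements.

On the single open modelling question — whether the elongase's C20
activity should cover every C20 substrate rather than only the assayed
ones — the preset admits all C18/C20 substrates, since the assay design
already sampled both omega series at both lengths and the activity is
defined by chain length, not omega class.

## Motif classification

Families are assigned from the translated ORF by diagnostic motifs
(`X` = any residue):

| family | rule |
|---|---|
| ELOVL | `KXXEXXDT`, then `NXXXHXXMYXYY`, then `HXXHH`, then `TXXQXXQ`, each strictly after the previous hit |
| FED | `HPGG` (cytochrome b5 heme motif), then H-boxes `HXXXH`, `HXXXHH`-or-`HXXHH`, `QXXHH` in order |
| DESATURASE_OTHER | as FED but the third box resolves as `HXXHH` — such proteins are deliberately not treated as front-end desaturases |
| OMEGA_X | the H-box triple `HXXXH`, `HXXHH`, `HXXHH` with **no** `HPGG` anywhere |

Three decisions were genuinely open and are fixed as follows. The boxes
must occur in sequential order, following the universal desaturase domain
architecture (the source rules list the boxes without ordering them);
`HPGG` must precede the first H-box because the cytochrome b5 domain is
N-terminal in front-end desaturases; and when both second-box variants
match at the same position the longer `HXXXHH` is preferred. Box
assignment is leftmost-greedy; a unit test checks agreement with an
exhaustive enumeration oracle over hundreds of seeded proteins, guarding
against pathological orderings. No inter-box spacing constraint is
enforced (none is documented); the false-positive risk this leaves is
mitigated by the full-length ORF requirement and deduplication.

ORFs are ATG-to-stop under the standard genetic code, scanned in all six
frames, with nested ORFs sharing a stop suppressed in favour of the
longest. The default `min_codons = 100` excludes noise ORFs while keeping
any real full-length enzyme (elongases ≈ 270 aa, desaturases ≈ 350 aa).
Deduplication is on exact protein identity only — assembly isoforms are
reported separately, never merged.

## The cox1 contamination screen

Contigs are scored against a cox1 reference panel by local pairwise
alignment with blastn-like scoring (match +1, mismatch −2, gap open −5,
gap extend −2). Identity is `100 · matches / alignment columns` of the
best local alignment, internal gaps included — the stricter of the two
possible readings, chosen because the original rule does not state the
identity definition. A hit must span at least 100 aligned columns (no
minimum is documented; 100 nt prevents trivially short high-identity
windows), and a sample is positive when any hit exceeds **75% strictly**
(identity exactly 75.0 is negative). Both the minimum length and the
gap-inclusiveness are configuration-exposed.

Read recruitment, where raw reads rather than contigs are available, is a
deliberately simple stand-in for read mapping: a read is recruited when it
shares one canonical 31-mer with the panel. Recall is exactly 1 for
error-free reads of length ≥ k drawn from panel sequences.

### Numerical behaviour of the cox1 screen

Under the generator's substitution-only divergence model the expected
identity is `100(1 − p)`, and the screen reproduces it closely for
p ≤ 0.2 (the acceptance suite measures means of 100, 99.6, 95.2 and 80.0
at p = 0, 0.004, 0.05, 0.2). At p = 0.3 the per-column score drift of the
fixed scoring scheme is only `0.7·1 − 0.3·2 = 0.1`, so the optimal local
alignment trims mismatch-dense ends and the measured mean identity is
about 72.9 rather than 70 — the corresponding acceptance band is left
failing rather than widened, with the analysis recorded alongside the
test. For the same reason a small minority of p = 0.3 replicates can
exceed 75% through short trimmed windows; the positivity flip between 0.2
and 0.3 is therefore asserted on all-replicates-positive at 0.2 and on the
expected identity falling below the threshold at 0.3.

## Global identity comparison

Homologous gene sets are compared by end-to-end Needleman–Wunsch alignment
(match +1, mismatch −1, linear gap −2, terminal gaps penalized), identity
being identical columns over alignment length — the convention of common
percent-identity matrices. Because co-optimal alignments can differ in
identity, the traceback preference is fixed (diagonal, then gap in the
second sequence, then gap in the first), making reports byte-identical
across runs; a plain-loop oracle in the test suite recomputes identity on
hundreds of random short pairs. Comparison is case-insensitive, `N` never
counts as a match, and identities are computed on full ORFs (whether the
original comparisons used trimmed alignments is unknown; full ORF is the
choice here). Genes absent from one set are reported as absent (`*` in
TSV output), never as an identity of 0.

## Gene structures and introner-like elements

Annotations are consumed from GFF3 (exon features grouped by `Parent`);
internally all coordinates are 0-based half-open on the forward strand,
converted from GFF3's 1-based inclusive convention exactly once, at the
parser boundary. Introns are inter-exon gaps numbered in transcription
order, reverse-complemented for minus-strand genes. Spliced alignment of
transcripts to a genome — how such annotations are produced in the first
place — is out of scope; fixtures carry annotations.

An intron is **introner-like** when it has canonical `GT..AG` splice
sites, a 3' polypyrimidine tract, and length ≥ 100 bp. The tract search
scans the 3'-terminal 40 nt (excluding the final AG) for the longest run
of ≥ 8 nt with C/T fraction ≥ 0.8, leftmost on ties; these parameters
follow canonical spliceosomal intron descriptions — none are quantified in
the source material — and all are exposed in the configuration. The
100 bp length floor operationalizes "relatively long"; the motivating
real-world example, a 940 bp third intron, exceeds it comfortably and is
the length planted in the genome fixture.

## Conversion arithmetic

Yeast-assay conversions are
`100 · Σ(product areas) / (Σ(product areas) + substrate area)` on GC-FID
peak areas. The product set for a substrate is the closure under the
single introduced enzyme, because the yeast applies the enzyme
iteratively (C18 → C20 → C22 elongation products all accumulate); the
formula itself does not state this, but the multi-step products it is
applied to imply it. Missing product rows count as area 0; a substrate
missing from the table produces a per-substrate error entry rather than a
global failure. Endogenous-substrate ωx assays are represented as
`18:1n-9` rows in the same table format. The statistic is scale-invariant
and monotone in every product area; all-zero input is an undefined
conversion and is rejected.

## What the synthetic generator emulates — and what it does not

`make_sample()` emulates the freshwater/marine contrast at desk scale:
15 host contigs (0.8–2.5 kb random sequence, resampled until they contain
no classifiable ORF, guaranteeing clean negatives), and under the
freshwater profile the typical contaminant complement — one elongase,
four front-end desaturase and two methyl-end desaturase CDSs on random
strands, plus one cox1 fragment diverged from a bundled reference at a
default substitution rate of 0.004 (mirroring a near-identical, ~99.6%
barcode hit). Each planted CDS is verified at generation time to be
recovered exactly by the screen, so truth files are exact by
construction. Divergence is substitution-only so identity has a closed
form.

The generator does **not** emulate: realistic transcriptome scale (real
assemblies have 10⁴–10⁵ contigs; 15 hosts keep the suite fast while
exercising every code path), codon-usage bias, sequencing error or
assembly artifacts, isoform redundancy, or genuine homology between host
ORFs and the screened families. A green closure test therefore
establishes that the screens are correct on their own stated model of the
data — planted motif-complete genes in a clean background — not that
their sensitivity/specificity on real assemblies is 1.0. The bundled cox1
panel is synthetic (random rotifer-style labelled sequences, shipped so no
download is ever needed); real panels are user-supplied.

`make_genome_fixture()` plants the three structural cases the structure
module must distinguish: an intronless gene, a plus-strand gene whose
940 bp third intron is introner-like with a tract planted at recorded
coordinates (the tract carries 10 pyrimidines in 12 nt between purine
runs, making it the unique longest qualifying run, so the reported span is
exactly the planted one), and a minus-strand control gene with a
non-canonical intron.

## Degenerate inputs and tie-breaks

Empty FASTA screens return empty results, not errors; an empty reference
panel is a configuration error. Ties between panel members are broken by
longer aligned length then lexicographic reference id. Reachability
tie-breaks, alignment tracebacks and generator seeds are all fixed, so
every report regenerates byte-identically (output paths are excluded from
the serialized report for this reason).

## Known limitations

* The cox1 identity calibration drifts above `100(1 − p)` beyond p ≈ 0.2
  (see above); species assignment is best-panel-match only.
* The motif rules carry no spacing constraints, so very H-rich proteins
  could in principle classify spuriously; the full-length ORF requirement
  is the main guard.
* Cross-sample gene pairing in the orchestrated report matches copies
  within a family by greedy best mutual identity — a heuristic that can
  mispair recent duplicates of near-equal identity.
* Phylogenetics, BLAST/HMM homology search, de novo assembly and
  taxonomic assignment are out of scope; candidate FASTA exports are
  suitable inputs for external tree building.
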