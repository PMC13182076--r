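---
title: "Characterizing a linear rDNA chromosome: models, detectors and design choices"
author: "rDNAscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a linear rDNA chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rDNAscan)
```

## The biological object

In myxomycetes such as *Didymium* and *Physarum*, the ribosomal RNA genes do
not sit on a nuclear chromosome. They are carried by a small linear,
extrachromosomally inherited rDNA chromosome present in on the order of a
hundred copies per haploid genome. A single such molecule packs a remarkable
amount of structure into ~20 kb:

* regular telomeric repeat arrays (`CCCTAA` on the forward strand at the
  left end, `TTAGGG` at the right end);
* a multi-kilobase **palindrome** in the non-transcribed spacer (NTS), whose
  nearly identical inverted halves can extrude a cruciform and which harbors
  two short replication-origin motifs (PRO1/PRO2) on opposite halves;
* direct-repeat arrays whose unit copies are similar but not identical;
* an **upstream promoter region (UPR)** organized as a tandem array of
  260 bp D-type units, each containing two short inverted-repeat motifs and
  an internal 140 bp palindrome;
* an rRNA transcription unit (external transcribed spacer, SSU rRNA gene,
  ITS-1, 5.8S, ITS-2, LSU rRNA gene, trailer) interrupted by self-splicing
  group I introns — one of which carries a homing endonuclease gene (HEG)
  that is itself interrupted by a tiny spliceosomal intron (I51) — plus a
  poly(A) site used by the intron-derived mRNAs.

`rDNAscan` implements, as reusable and tested components, the computational
characterization of such a chromosome: building a fully specified synthetic
replica with ground truth, rediscovering the repeat architecture blind from
sequence, estimating copy number from read depth, and extracting RNA
processing evidence from 3'-tag reads.

## The synthetic chromosome and what it emulates

`defaultPlan()` encodes the architecture as an ordered list of parametrized
segments; `buildChromosome()` realizes it into a concrete sequence plus a
`GRanges` truth annotation. The default plan satisfies every printed total
simultaneously: a 20,300 bp chromosome with a 11,300 bp transcription unit;
ETS 1,483 bp; SSU rRNA 1,916 nt split by the 1,436 nt intron S956-1 (whose
HEG contains the 51 nt I51); 5.8S 154 bp; mature 26S 3,702 bp split by the
introns L1949 and L2449; a 4,200 bp NTS palindrome; a 5 × 260 bp UPR.
Where only totals are published, the internal splits (e.g. exon split
956/960 nt around S956-1; 26S exons 1,100/500/2,102 bp; ITS-1 500 bp;
ITS-2 300 bp; trailer 59 bp; intron sub-layout 250 nt group I ribozyme
core, 180 nt lariat-capping ribozyme, 955 nt HEG) are package defaults
chosen once so all published totals hold; every one of them is configurable
through the plan.

Several generator choices deserve explanation:

* **Unit sequences are frozen stand-ins.** The real repeat-unit sequences
  are only shown graphically in the literature, so the default A–N units,
  the D-type unit, the IR motifs and the 15 bp PRO motif are fixed arbitrary
  sequences of the correct lengths, generated once from an internal seed
  that is independent of user seeds. The detectors test geometry and
  identity structure, not literal sequence content.
* **The planted 140 bp palindrome has a well-defined maximal span.** Within
  the master D-unit, the four base pairs flanking the palindrome on each
  side are forced to be non-complementary. Without this, whether the
  "true" palindrome is 140 or 142 bp would depend on coincidental flanking
  complementarity, and a span assertion would be ill-posed.
* **Divergence is substitution-only.** Unit copies and the palindrome's
  second half are independently mutated at a per-base substitution rate
  (default 0.01), reproducing the similar-but-not-identical character of
  real arrays. Indels are deliberately out of scope; this keeps ungapped
  comparison exact and the in-package mappers gapless.
* **Origin motifs are re-stamped after divergence**, so PRO1 and PRO2 are
  exact copies in both palindrome halves, as the planted-motif contract
  requires.
* **3'-tag reads are drawn from processed species**, not from the genome:
  the ligated SSU rRNA (RNA1), 5.8S, the ligated 26S, the polyadenylated
  unprocessed HEG transcript (RNA2, I51 retained), the mature HE mRNA
  (RNA3, I51 removed), and a 5' ETS fragment. Polyadenylated species get a
  25 nt untemplated tail at the truth poly(A) site and are sampled with an
  exponential 3'-end bias (mean offset 300 nt), mimicking a 3'-tag
  library's preference. The ETS fragment is sampled from the transcript 5'
  end with a 0–20 nt ragged start, so pooled coverage onset marks the
  transcription start exactly. No species touches the NTS, which is what
  makes "zero NTS coverage" a meaningful end-to-end check. Default stage
  mix (identical across the four life stages): rRNA-derived 0.90 (RNA1
  0.40, 26S 0.40, 5.8S 0.10), RNA3 0.06, RNA2 0.03, ETS fragments 0.01.
* **Long reads have uniform coverage.** Read starts are sampled over the
  extended range and clipped at the reference ends, so realized coverage is
  uniform at the target depth along the whole reference and reads reaching
  a telomere are truncated there, as telomere-to-telomere reads are. If
  reads are instead confined to lie inside the reference, interior coverage
  exceeds the nominal depth by L/(L − readLen + 1) — a factor that differs
  between a 20.3 kb target and 50 kb backgrounds and visibly biases a
  depth-ratio estimator at desk scale.

What the generator does **not** emulate: realistic long-read error profiles
(indels, homopolymer artifacts, chimeras), RNA secondary structure,
low-complexity/homopolymer tracts in the NTS, expression differences
between life stages, and assembly. A green test suite therefore
demonstrates that the detectors and estimators recover a known architecture
under substitution-only noise at desk scale — not that they are robust to
every artifact of real ONT or Illumina data.

## Blind repeat discovery

`selfDotplot()` computes maximal merged diagonal runs of exact k-mer
self-matches (default k = 12, minimum run 20 bp) in sense and antisense
orientation — the machine-readable form of a self-identity dot plot.
Substitutions split exact runs into collinear pieces separated by a few
bases; pieces on the same (anti)diagonal are merged across gaps up to 25 bp
(two substitutions within one word length). k = 12 with a 20 bp minimum run
suppresses random matches at the 20 kb scale (expected count ≪ 1) while
still resolving all planted arrays; 15 bp motifs are the motif search's
job, not the dot plot's.

`callPalindromes()` groups antisense runs by their antidiagonal axis
(±3 bp), then sub-clusters by q-proximity (gap ≤ 100 bp) — necessary
because symmetric pairs of inverted repeats across tandem-array units share
an axis by construction without forming one palindrome. A candidate's runs
must cover at least half of the claimed arm and the arm identity must reach
0.8; arms are refined by mismatch-tolerant outward extension (a mismatching
pair is bridged only when one of the next two outward pairs matches, and
arms end on a matching pair), then trimmed to equal length about the axis.
`halfIdentity()` is the ungapped fraction of positions at which the left
arm equals the reverse complement of the right arm.

`findTandemArrays()` sweep-clusters sense runs whose footprints overlap by
more than 4 bp (1–2 bp chance extensions across the boundary of adjacent
unrelated arrays must not merge them), scores candidate offsets by
aggregated run length (±3 bp tolerance) and takes the smallest offset
reaching 95% of the best score as the period — the canonical minimal unit,
so a five-copy array reports 260, not 520. Edges are refined against the
period-shifted partner sequence with a +1/−1 score, accepting an extension
only at a net gain of at least 3 matches; this recovers up to k − 1 bases
lost to a mutated edge k-mer while random flanking sequence (expected
drift −0.5/base) is essentially never entered. Unit boundaries are phased
to maximize cross-unit identity, and the reported identity is the mean over
all unit pairs by direct comparison.

`detectTelomeres()` reports, per chromosome end, the maximal terminal
window whose motif purity reaches 0.8 (window trimmed to the outermost
motif-covered base; at least 3 copies), with eroded terminal and inner
partial copies counted fractionally. `longestExactMatch()` finds the
longest common exact substring between a query motif and a region on both
strands by binary search over the length, and returns all maximal hit
positions — this is how the PRO1/PRO2 origin motifs are located in the two
palindrome halves.

## Copy number from depth ratios

`simulateCopyNumberRun()` reproduces the depth-ratio experiment at desk
scale: three 50 kb single-copy background contigs at mean depth 5, the
rDNA chromosome at 132 times that, substitution errors at 2%.
`mapLongReads()` is a deliberately minimal exact-seed chain mapper
(strided 15-mers, diagonal voting, ties to the leftmost coordinate) —
sufficient for gapless reads and fully testable; `estimateCopyNumber()`
divides the target's median per-base depth by the pooled background
median.

Two numerical choices matter at these depths:

* **Per-base median rather than binned median.** Per-base background depth
  is an integer count with median exactly equal to the target depth,
  whereas the distribution of 100 bp bin means at depth 5 is right-skewed
  and its median sits 3–7% below the mean, which inflates the ratio by the
  same amount. The binned track remains available in `depthProfile()` for
  display and bedGraph export; only the estimator's summary is per-base.
* **Read length 250 bp for this scenario.** The sampling stability of an
  integer median depends on the number of read-length-sized independent
  stretches: with 1 kb reads the 150 kb background supplies only ~150,
  and the median occasionally snaps from 5 to 4 (a single such flip moves
  the estimate from ~132 to ~165). At 250 bp there are ~600 independent
  stretches and the flip probability is negligible, with no change to the
  estimator itself. Real data sidestep the issue by having background
  depths an order of magnitude higher.

## RNA evidence

`mapTagReads()` anchors each read by exact 20-mers at its 5' end and (for
reads whose 5' block is shorter than an anchor word) at its 3' end, then
evaluates contiguous and two-block placements. Annotated candidate introns
are tried first — which also pins donor/acceptor coordinates when flanking
bases are coincidentally shared, the classic shift ambiguity — with an
exact de novo suffix search as fallback. Untemplated 3' A-runs are
soft-clipped before placement and returned base by base where the
reference itself continues with A, so the recorded tail counts genuinely
untemplated adenosines only.

`callJunctions()` aggregates identical reference gaps with support counts
and flags *perfect ligation* when a gap matches an annotated intron
exactly. `callPolyA()` clusters tailed alignment ends (radius 5 bp,
minimum tail 10 nt, minimum support 2). `classifySpecies()` partitions
reads by their defining evidence (I51 junction → RNA3; unspliced I51
coverage → RNA2; S956 junction or SSU placement → RNA1; and so on); HEG
reads with no I51-informative overlap cannot distinguish RNA2 from RNA3
and are counted as ambiguous rather than guessed. Gene-level spans are an
input to `assembleAnnotation()` (in the synthetic pipeline, the truth's
gene rows), mirroring homology-based gene placement in practice; intron
coordinates, the transcription start (pooled coverage onset), spacer spans
and the whole repeat architecture are inferred from the data. The
transcription terminator has no direct 3'-tag evidence and is taken from
the plan when characterizing synthetic data (flagged as inferred
otherwise).

## Degenerate inputs and tie-breaks

Non-ACGT characters are skipped at the k-mer level. Reads wholly inside a
perfect tandem repeat (e.g. a telomere array) are inherently ambiguous;
the mapper resolves them deterministically to the leftmost best diagonal.
Overlapping palindrome calls resolve to the largest span; overlapping
periods to the smallest offset within 95% of the best score; an empty
alignment set yields an all-zero profile with median 0; a zero background
median or an all-zero abundance vector is an error, not a silent zero.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
20.3 kb default chromosome with 4 × 5,000 tag reads, and the copy-number
simulation on 170 kb of reference at background depth 5 (about 55,000
reads per replicate, 20 replicates for the averaged estimate). These sizes
were chosen so each stage's sampling error is far below the tolerances
being asserted while a complete run stays in the minutes range on one CPU.

## Known limitations

Quadratic-flavored scans and R-level loops cap practical input size around
tens of kilobases (by design — suffix structures are a non-goal at n ≈
20 kb). The mappers are gapless: indels, which real ONT reads have in
abundance, are out of scope. Species classification reports evidence-based
counts, not abundance estimates; a deconvolution of RNA2/RNA3 from
ambiguous tail reads would require a model of the 3'-bias that the package
deliberately does not fit. The cruciform-formation hypothesis for the NTS
palindrome is represented only by its sequence prerequisites (the
palindrome call, its arm identity, and the PRO motif coordinates), not by
any structural free-energy modelling.
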