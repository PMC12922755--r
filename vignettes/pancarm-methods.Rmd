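---
title: "pancarm: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pancarm: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Coordinate model

All coordinates are 1-based inclusive; BED files are converted from
0-based half-open on read and back on write. The genome is hg19, autosomes
only (chr1-chr22), tiled into 500-kb bins anchored at position 1 of each
chromosome, so printed locus boundaries such as 227,000,001 fall on bin
edges. The last bin of a chromosome may be shorter. Arm boundaries come
from a packaged table of chromosome lengths and centromere midpoints
derived from the UCSC hg19 cytoband/gap tables; a bin that straddles the
centromere belongs to no arm and is excluded from arm-level statistics
(the upstream sources do not state how such bins were handled, so we
exclude rather than guess). Acrocentric short arms (13p, 14p, 15p, 21p,
22p) carry no interpretable signal at this resolution and are flagged
excluded by default (configurable).

## 2. Arm-level calling

The input is a bins x samples matrix of discrete copy-number calls
(G/N/L) as emitted by low-pass WGS segmentation. Two rules operate on each
(sample, arm):

* **Full-arm rule**: a full-arm gain requires gained bins >= arm bins − 3,
  i.e. at most 3 non-gained bins on the arm; full-arm losses are defined
  analogously. The boundary is inclusive. A degenerate guard requires at
  least one gained bin so that arms of <= 3 bins are never called "full"
  while all-neutral; real arms have dozens to hundreds of bins, so the
  guard never triggers on the packaged grid.
* **Minimum-run rule**: an arm counts as gained at all (full or partial)
  when it carries a run of >= `min_run` consecutive G bins. The upstream
  sources define only the full-arm rule; their criterion for counting an
  arm as gained at all is unstated. Default `min_run = 6` (3 Mb): long
  enough to suppress isolated noise bins, short enough to capture the
  ~3-Mb critical regions that motivate the analysis. It is exposed in
  every interface, and sensitivity to `min_run = 1` vs `6` is a one-flag
  comparison.

When an arm has both a qualifying gain run and loss run, both are recorded
in the counts and GAIN takes precedence for the single reported state.

Sample QC: a sample is dropped iff its GC-correction MAD >= 0.15 (the
source pipeline used strict < 0.15). A sample whose observed/expected
segmentation variance ratio exceeds 2 is *flagged*, never auto-dropped —
the modeled cohorts kept such samples with a note, and "much larger
observed variance" was never quantified upstream.

Frequency denominators count tumors (samples), not patients; a patient
contributing two lesions contributes twice, as in the modeled study.

## 3. Synthetic cohort: the stated world

The generator's defaults are the cohort conditions the modeled study
reports; each is a config key and all are overridable.

* **Grade mix** (`n_per_grade`): NORMAL 45, LG PanIN 65, HG PanIN 37,
  LG IPMN 76, HG IPMN 70, MCN 9, SCA 10, PDAC 535.
* **1q gain probability per grade**: 0.07 / 0.49 / 0.33 / 0.36 / 0.40 for
  LG PanIN / HG PanIN / LG IPMN / HG IPMN / PDAC. (One summary sentence in
  the source swaps the two IPMN figures relative to its own detailed
  counts; we follow the detailed counts.)
* **Context events**: PDAC per-arm rates 8q gain 0.467, 9p loss 0.604,
  17p loss 0.699, 18q loss 0.742 (the reported PDAC frequencies). For HG
  precursor grades each of the four context arms gets probability 0.242
  and for LG grades 0.026, calibrated so the chance of >= 1 context event
  is ~0.67 and ~0.10 respectively — the reported context fractions. MCN
  samples never gain 1q but carry moderate other-arm rates; SCA samples
  only lose 3p (rate 0.5). NORMAL samples are always copy-neutral.
* **Focal share**: a 1q gain is focal (subchromosomal) with probability
  0.34, an 8q gain with probability 0.50. A focal 1q gain covers both
  anchor loci / 1q23.2 only / 1q42.13 only / neither with probabilities
  0.3235 / 0.3824 / 0.2353 / 0.0588, derived from the reported 77/13/8/2
  joint split after removing the 66% full-arm share (full-arm gains are
  all "both"). A focal 8q gain covers 8q24.21 with probability 0.86
  (93% of all-8q-gained tumors cover it; full arms contribute 50%).
* **Whole-genome doubling**: probability 0.45 for PDAC (the fraction
  reported for PDACs in the WGD literature the source cites), 0.2 for HG
  grades, 0.05 for LG grades, 0 otherwise. WGD sets base ploidy 4; events
  add to the doubled genome.
* **Purity**: uniform on (0.4, 0.9) for neoplastic grades, 1 for NORMAL.
  The source gives no per-sample purities beyond noting careful
  dissection and occasional "low tumor cellularity"; this range is
  asserted, not inferred, and is a config knob.
* **Bin noise**: i.i.d. Gaussian log-ratio noise, sd 0.05 (the source's
  empirical noise is unstated).
* **Gain magnitude**: +1 copy per event. Reported per-tumor 1q copy
  numbers range 3-7; a single extra copy is the modal, conservative
  choice and keeps the rendering model simple.

### 3.1 Focal segment lengths (design deviation)

Segment extensions beyond the anchor locus are exponential with mean
10 Mb rather than uniform over the arm. Uniform endpoints make the
expected gain fraction *between* the two 1q anchors (~0.63) exceed the
fraction at the weaker anchor itself (~0.56), decreasing monotonically
from 1q23.2 to 1q42.13 — a geometry in which no threshold- or
local-maximum-based peak detector can ever isolate the second peak, and
which contradicts the two-peak profile structure observed in the real
cohorts. Real focal gains are short-tailed; the exponential tail produces
an inter-anchor valley (~0.40) and makes both anchors recoverable.
Segments always span >= 6 bins (so every planted event is recoverable at
the default `min_run`) and always leave >= 4 non-gained bins on the arm
(so a planted focal event is never misread as full-arm).

### 3.2 Rendering and relative-copy-number blindness

A bin with true copies $c$ at purity $p$ gets raw log-ratio
$\log_2((p c + 2(1-p))/2)$ plus Gaussian noise. Median normalization
subtracts the genome-wide median before discretization, emulating relative
calling. Discretization assigns the integer state whose expected centered
log-ratio at that purity is nearest, with two consistency choices:

* **Median-state anchoring.** The candidate state grid is centered on the
  sample's *median state* (the state whose expected raw log-ratio is
  nearest the empirical median), and G/N/L are assigned relative to that
  state. This is what relative callers do (they call against estimated
  sample ploidy) and it is the only self-consistent reading: on a
  diploid-anchored grid, a 4-to-3 loss in a genome-doubled sample sits
  exactly halfway between relative states 1 and 2 and can never be
  called. A uniformly tetraploid genome still renders all-neutral — the
  blindness mechanism — because its median state is 4.
* **Segment-level discretization** (default; per-bin mode available as
  `discretize = "bin"`). Bins of one true segment share the state nearest
  the segment's mean centered log-ratio. The pipeline's real input is
  segmentation output, in which independent per-bin state flips do not
  occur; per-bin discretization at the default noise would flip > 3 bins
  on a ~250-bin arm often enough to demote ~10% of true full-arm gains to
  partial, which misrepresents the data source being emulated. The per-bin
  log-ratios themselves always carry the full noise.

### 3.3 FISH, expression and duplex reads

FISH: each nucleus reports Binomial(true copies at the probe locus,
p_detect) signals, p_detect default 0.95; counts are uncapped at
generation (capping at 10 is a scoring-stage rule). FISH sees pure
neoplastic nuclei — the modeled protocol scored histologically identified
cancer nuclei — with an optional admixed normal-nucleus fraction.

Expression: responsive genes get baseline + effect_size x (copies − 2) +
Gaussian noise (defaults 2 and 0.5); non-responsive genes are noise only.
The cohort panel places one third of genes in each 1q critical region
(half of them responsive) and one third elsewhere (never responsive).

Duplex reads: each template gets a distinct random 14-nt UID and one
Watson and one Crick family; family size is 1 + Geometric(0.4) (the
source states no family-size distribution). Sequencing errors are i.i.d.
per read per base on the insert, strand-independent, default 1e-3. Errors
are not placed in the UID itself: a UID error would create a spurious
singleton family, harmless to the caller and adding nothing testable.
UID collisions are re-drawn at generation (probability ~ n²/2·4⁻¹⁴);
the caller does not attempt to resolve collisions in real data.
The amplicon panel and the variant-annotation lookup are synthetic
stand-ins (`synthetic_amplicon_panel()`, `synthetic_cosmic_lookup()`):
37 amplicons across KRAS/NRAS/GNAS/CDKN2A/TP53/SMAD4 at their real hg19
gene starts with randomly generated 120-bp references and one hotspot
each.

Driver mutations in precursor lesions: every precursor gets KRAS (p 0.8)
or GNAS, matching the reported 100% initiator rate; a tumor-suppressor
mutation (CDKN2A/TP53/SMAD4, uniform) is added with probability 0.24 given
a planted 1q gain and 0.173 otherwise, consistent with the reported
cross-tab (76% of 1q-gained lesions without TS mutation; 65% of TS-mutant
lesions without 1q gain).

### What a green test does not establish

The generator draws arm events independently per arm (no karyotype-wide
correlation beyond WGD), has no subclonal mixtures, no wavy GC artifacts,
no alignment or FFPE artifacts, no indel errors, and knows its own segment
boundaries. Green recovery tests establish that the analysis rules are
implemented correctly and are recoverable under the stated noise model —
not that they would perform identically on real low-pass WGS.

## 4. Localization

Gain-fraction profiles have an explicit denominator mode because the
modeled figures restrict to subchromosomal gains while the locus-inclusion
percentages include full-arm gains: `partial_only` selects GAIN and not
full-arm; `any_gain` selects all GAIN samples.

`detect_peaks` reports maximal runs of bins within `rel_tol` of the global
maximum, merging runs closer than `merge_gap_bins` (default 4 bins = 2 Mb).
Default `rel_tol = 0.02` reports the plateau of the dominant peak — the
analog of the printed peak spans. Recovering *both* planted 1q peaks needs
`rel_tol > 1 − 0.56/0.71 ≈ 0.21` (the planted heights are both + A_only ≈
0.71 and both + B_only ≈ 0.56 of the partial-gain denominator); the
acceptance checks use 0.25, a value derived from that configured geometry
before any test was run, not fitted to one.

Locus inclusion uses a strict majority of overlapping bins (a multi-bin
locus counts as gained when more than half its bins are G); the stricter
all-bins rule is a flag. The source does not define how a multi-bin locus
was scored; majority is monotone (N→G flips never retract an inclusion)
and robust to a single boundary bin.

The dosage-expression screen is a Pearson correlation t-test per gene
(alpha 1e-5), the simplest test consistent with "correlated"; Spearman is
available. Zero-variance genes are flagged and excluded from significance
calls rather than silently dropped.

## 5. Statistics

`fisher_exact_two_tailed` enumerates the hypergeometric distribution over
all tables with the observed margins and sums the probabilities not
exceeding the observed table's probability, with a 1e-12 relative tie
tolerance (the method of small p-values; `stats::dhyper` supplies the pmf,
the tail rule is implemented here). Degenerate margins give p = 1. The
test suite checks it against both an independent `lchoose`-based
enumeration and `stats::fisher.test` on 1,000 random tables, and verifies
transpose/row-swap/column-swap invariance and type-I conservativeness.

Pairwise event independence reports odds ratios with a +0.5 Haldane
correction when any cell is zero (p-values are never computed on corrected
counts) and raw p-values by default — the modeled analysis used the
pairwise table descriptively; Benjamini-Hochberg adjustment is an option.

For the context comparison, the two HG precursor strata (HG PanIN +
HG IPMN) are pooled when reconstructing the printed 29/14 table; the
source is consistent with but does not state this pooling, so the
reconstruction is documented rather than asserted.

## 6. FISH scoring and concordance

Counts above 10 are recorded as 10; capping cannot change the >= 3 or >= 4
tail fractions. Two analysts' nuclei are pooled (concatenated), not
averaged — the modeled protocol names two independent analysts without a
reconciliation rule, and pooling is order-invariant. "Most nuclei" is
formalized as frac_ge3 > 0.5, strict. A FISH-positive/WGS-negative sample
is attributed to low purity when tumor fraction < 0.2 (the source says
"low tumor cellularity" without a number) and otherwise to the
relative-copy-number blindness of WGS; a WGS-gain/FISH-negative sample
falls in the same relative-CN class, the source not naming a separate one.

## 7. Duplex calling

Boundaries follow the wording exactly: consensus > 80% in both strand
families (strict, so 8/10 fails); mutant templates "more than two" = >= 3
(a >= 2 relaxation flag exists for sensitivity analyses); coverage >= 5
counted in *template molecules* (duplex groups), consistent with the
template-molecule vocabulary of the rules; position >= 30 bp from both
molecule ends; catalog support >= 2 annotations with a confirmed-somatic
flag (a genome-wide-study-only restriction is selectable); assessability
>= 10 KRAS templates, read as inclusive. `min_reads_per_strand` defaults
to 1 (no family-size floor is stated; real deployments often use >= 2, so
it is exposed). Strand assignment is by insert orientation relative to the
UID-bearing read (fewer mismatches against the reference than its reverse
complement; an exact tie — possible only for palindromic references —
calls WATSON).

## 8. Pipeline

`run_pipeline` chains simulate/ingest → QC → arm calls → frequencies →
localization → co-occurrence → FISH → duplex, records the seed and every
threshold in the report provenance, aborts with the failing stage's name,
and is byte-reproducible from config + seed. Every threshold named in the
rules above is a single documented config key (`run_config()`).

## 9. Known limitations

* No segmentation algorithm is implemented; the simulator emulates
  segmenter *output*, and real ichorCNA/QDNAseq matrices are ingested,
  never recomputed.
* Absolute-ploidy inference from WGS is out of scope (the blindness it
  causes is modeled and measured instead).
* The duplex caller consumes amplicon-anchored reads (coordinate matching
  in the synthetic setting); plugging in a real aligner is possible but
  not implemented, and indels are not modeled.
* Expression screening runs on synthetic or user-supplied matrices; no
  external expression database is downloaded or harmonized.
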