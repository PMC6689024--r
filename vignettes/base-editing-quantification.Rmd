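---
title: "Quantifying and characterizing cytosine base editing from amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and characterizing cytosine base editing from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescope)
```

## The problem

Cytosine base editors (CBEs) are deaminase–nCas9 fusions that convert C·G
pairs to T·A without double-strand breaks. Different deaminases, and
different fusion geometries of the same deaminase, edit different parts of
the protospacer with different efficiency, favour different sequence
contexts around the target cytosine, and leak to off-target loci to
different degrees. Characterizing an editor therefore means answering four
questions from targeted amplicon deep sequencing of edited cells: *where*
in the protospacer it edits, *how much*, *in which contexts*, and *how
specifically*. `bescope` implements that workflow end to end, together
with a read simulator that provides exact ground truth for validating
every stage.

## Coordinate system and quantification window

All results are reported in protospacer coordinates: positions 1–20 run
5′→3′ along the protospacer, the PAM occupies 21–23 (for SpCas9), positions
downstream of the PAM continue 24, 25, …, and positions upstream of the
protospacer are −1, −2, … with −1 immediately 5′ of position 1. There is
**no position 0**: upstream indices are offset by one relative to naive
subtraction, so that "position −1" names the base one step before position
1, matching how near-PAM-distal edits are conventionally reported. The
no-zero choice is the one genuinely open convention here; it is fixed in
one internal helper pair (`cp_to_offset()` / `offset_to_cp()`) and every
mapping goes through it.

Base conversion is quantified from 30 nt upstream of the PAM's 5′ end to
10 nt downstream of its 3′ end. For a 20-nt protospacer and 3-nt PAM that
is 43 positions (−10…−1, 1…33): the 30 upstream positions are the 20
protospacer bases plus 10 further upstream. Measuring the window from the
PAM rather than the protospacer keeps its length at `30 + pam_len + 10`
for any PAM. All calls are made on the **protospacer strand**: for a site
annotated on the − strand of its amplicon, a C→T event is a G→A on the
amplicon forward strand, and the package mirrors indices and complements
bases internally (`cp_to_amplicon_index()`, `context_at()`). Amplicon
references must be unambiguous A/C/G/T; IUPAC ambiguity codes are rejected
rather than expanded, since amplicon references are short and known
exactly (the PAM *annotation* in site files may use codes such as `NGG`).

## Read processing

`quantify_sample()` chains four steps, each available separately:

1. **Demultiplexing** (`demultiplex()`): a read belongs to the sample whose
   barcode exactly matches its prefix (0 mismatches); the barcode is then
   stripped, and non-matching reads are counted as unassigned. Exact
   matching is the simplest defensible rule for short ligated barcodes;
   the counts are conserved (assigned + unassigned = input) and checked in
   the tests.
2. **Quality trimming** (`quality_trim()`, default `q_min = 15`): bases
   are removed from the 3′ end while their Phred score is below the
   threshold. 3′-anchored trimming is the standard read-quality operation
   for quality that decays along the read; interior bases are never
   removed, and a fully trimmed read is simply discarded downstream.
3. **Placement** (`place_reads()`): the read's first 20 bases must match
   the amplicon (either strand) exactly and uniquely; the full-length
   alignment at that locus is then accepted if its mismatch fraction is at
   most 0.2. The cap tolerates a fully edited window plus sequencing error
   on a typical read while still rejecting foreign sequence; reads with
   ambiguous seeds (two or more hits) are discarded and counted. Because
   the seed is exact, reads should carry a short unedited flank 5′ of the
   window — the simulator adds 25 nt by default — so that editing itself
   cannot destroy the seed; seed losses from sequencing error are
   independent of editing state and therefore do not bias frequencies.
   Reverse-strand placements are reverse-complemented into forward
   orientation before tabulation.
4. **Tabulation** (`tabulate_reads()`): every covered window position
   increments the count of the observed base, read on the protospacer
   strand. Depth varies by position when reads are partial. Positions
   with depth 0 are reported as **missing, never as 0%** — a frequency of
   0 is evidence of non-editing, absence of coverage is not. Only
   substitutions are tabulated; the frequency formula has no indel term,
   and the simulator generates none.

The conversion frequency at a reference-C position is
`count(T) / depth` — base-conversion reads over total reads.

## The read simulator and what it does (not) model

`editor_profile()` defines a generative editor: a per-position editing
probability `p_edit` (positions absent from the map are 0), multiplicative
modifiers for the upstream dinucleotide context (`AC`, `CC`, `GC`, `TC`;
optionally also downstream `CA`…`CT`, default all 1), a uniform per-base
substitution error `e` (default 0.001, about Q30 chemistry after
filtering; must be < 0.25), a constant base quality (default Q37) and an
optional low-quality 3′ tail for trim testing. The effective editing
probability at a C is `q = min(1, p_edit × context multipliers)`; clipping
events are counted and reported. The expected observed T fraction at that
C is exactly

```
E[T frequency] = q (1 − e) + (1 − q) e / 3,
```

an edited read shows T unless an error moves it away, and an unedited read
shows T only through one of the three equally likely substitutions. This
closed form (`expected_t_frequency()`) is the oracle for all recovery
tests. Upstream-context modulation is the default because the dominant
context signal for characterized deaminases is the base 5′ of the edited C
(e.g. preferences of the form `TC/AC>CC>GC`); downstream modulation is
available but off by default.

Deliberately **not** modeled: co-editing correlation between positions
within a read (real deaminases are processive — frequencies remain
unbiased but across-position correlations are absent here), indels, PCR
duplicates, paired-end structure, and Cas9-independent background
deamination. Passing recovery tests therefore validates the counting and
statistics machinery, not those aspects of real libraries. Editing events
are independent per read and position; sequencing error is
substitution-only and uniform.

`make_profile_library()` bundles four archetypes used throughout the
package: `forward` (support 1–8), `backward` (9–13), `broad` (1–14) — the
canonical forward-shifted / backward-shifted / broad-range window shapes —
and `gc_averse` (broad support, GC multiplier 0.1), all at editing
probability 0.6, a typical efficiency for active editors. Reads default to
10,000 per sample (a realistic per-amplicon depth for targeted
sequencing; recovery tests use 20,000 where tight binomial bounds are
asserted), spanning the full window plus 25/12 nt flanks.
`simulate_site_counts()` draws the per-position multinomial counts that
read-level simulation induces when every read covers the window; it is
used for the 1,000-replicate calibration studies where generating reads
would add only run time, and the equivalence is checked in the tests.

## Editing windows and classification

Within one sgRNA, frequencies are normalized by dividing by the maximum —
the best-edited C becomes exactly 1 (`normalize_sgrna()`); an sgRNA with
no editing at all is flagged and excluded rather than normalized by 0.
Two positional summaries follow:

- the **editing scope** is per-sgRNA and *inclusive*: positions with raw
  frequency ≥ 0.40 ("at least 40%");
- the **comprehensive editing window** is per-editor and *strict*:
  positions whose mean normalized efficiency across the panel *exceeds*
  0.6. The per-position mean averages only over sgRNAs that actually
  carry a C at that position — averaging in zeros for absent Cs would
  make the window depend on panel composition rather than on the editor.
  The CEW is kept as a set (interior gaps are preserved), with min/max
  used only for classification.

`classify_editor()` turns a CEW into a label with three configurable
rules, applied in order: an empty window is `inactive`; a window spanning
≥ 12 positions, or reaching both ends (start ≤ 2 and end ≥ 9), is
broad-range `BRCBE`; otherwise start ≥ 7 is backward-shifted `BSCBE`, and
anything else forward-shifted `FSCBE`. These cutoffs reproduce the
canonical assignments of characterized editors (windows like 1–8 forward,
9–13 backward, 1–14 broad); they are exposed as parameters because the
boundary between "forward but long" and "broad" is a judgement call, and
windows such as 1–9 sit on it.

## Substrate preference

Positions are eligible when at least one C site there reaches ≥ 0.8
normalized frequency; *all* C sites at eligible positions enter the
analysis (the weaker sites at a strong position are exactly the
informative ones for context effects). Values are compared on the
normalized scale so that sgRNAs of different absolute efficiency are
comparable. Sites are grouped by upstream (`NC`) and, separately,
downstream (`CN`) dinucleotide — both directions are always computed and
reported, as there is no principled reason to pick one a priori — and each
direction is tested by classical one-way ANOVA (`one_way_anova()`, via
`stats::aov()`; an independent explicit sum-of-squares implementation,
`anova_bruteforce()`, cross-checks it to 10⁻¹⁰ in the tests). Group
means are ranked into a preference string; means closer than 0.05 are
tied into `/`-tiers (an invented but configurable tolerance — the scale
is normalized frequency, so 0.05 is a 5-point difference on the best
site), and a non-significant ANOVA (p ≥ 0.05) reports `N.S.`. No
multiple-testing correction is applied across editors by default,
matching common practice for these per-editor characterizations.

Two statistical cautions, both visible in the calibration study
(`preference_type1_study()`): normalization ties the values of one sgRNA
together through their shared maximum, so ANOVA's independence assumption
holds only approximately — with the balanced built-in panel (each sgRNA
contributes one site per context, five sgRNAs) the block structure cancels
from the between-group means and the realized type-I error stays near the
nominal 5% (the acceptance run reports it, typically 4–8% over 1,000
replicates). And with few sites per group the test has power only for
strong effects; the GC-averse archetype (10× multiplier difference) is
detected with GC ranked last in ≈100% of runs, but subtle preferences
need larger panels.

## Specificity

For an on/off-target pair, `onCh` and `offCh` are the highest C→T
frequencies anywhere in each site's own 43-bp window (off-target sites are
imperfectly matched protospacers with their own PAM and coordinates), and

```
specificity = (onCh − offCh) / onCh.
```

The score is 1 for a silent off-target, 0 when both are edited equally,
and negative when the off-target is edited more — reported with the label
`N.Sp.` ("no specificity"). An on-target below `min_activity` (default
0.05 — a deliberate operationalization of "no obvious activity", which is
otherwise undefined; logged in the manifest) yields `no-activity` instead
of a meaningless ratio. When one on-target has a panel of off-targets,
per-pair scores are primary and two aggregations are emitted side by
side — the worst per-pair score and a pooled score against the panel's
maximum `offCh` — because collapsing a panel to one number is itself a
reporting choice.

## Numerical and design choices

- **Determinism**: every simulation takes an explicit seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds from one
  master seed, and re-running a configuration reproduces byte-identical
  TSVs. Tests assert this at the file level.
- **Thresholds** (trim Q15; scope ≥ 0.40; CEW > 0.6; preference ≥ 0.8;
  significance 0.05; `min_activity` 0.05; placement seed 20 nt, mismatch
  cap 0.2) all live in `run_config()` and are recorded in the run
  manifest. Scope is inclusive and CEW strict by definition of the two
  rules; tests pin both boundaries.
- **Ties**: the position of the highest conversion breaks ties toward the
  smallest position; normalization maps all tied maxima to 1; preference
  tiers use the 0.05 tolerance above.
- **Degenerate inputs**: zero reads, zero-coverage positions, all-zero
  sgRNAs, single-group ANOVAs and unpaired specificity sites all have
  defined non-crashing behaviour (flags, `NA`s with status attributes, or
  early configuration errors), exercised in the tests.
- **Study sizes**: validation studies use 10,000–20,000 reads per sample,
  20 seeds for exact CEW recovery, 100 runs for classification and
  preference recovery, and 1,000 replicates for ANOVA calibration —
  large enough for the binomial bounds asserted, small enough that the
  whole suite runs in minutes on one CPU.

## Limitations

Placement is exact-seed based and intended for synthetic or clean amplicon
data; heavily degraded 5′ ends defeat it, and an external aligner would be
the right tool for real libraries with adapters or indels. Indels are not
called at all. The classification rule is a deliberately simple interval
rule on the CEW; editors with genuinely bimodal windows will land on
whichever side their extremes dictate. Preference conclusions from small
panels are preliminary by nature — the balanced built-in panel has five
sites per context, enough to detect strong effects only.
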