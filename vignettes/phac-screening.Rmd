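---
title: "Degenerate-primer screening of phaC synthase classes: models and methods"
author: "phascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate-primer screening of phaC synthase classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phascreen)
```

## The screening problem

Polyhydroxyalkanoate (PHA) synthases fall into four classes (I-IV)
distinguished by operon structure and subunit composition, and the
*phaC* gene encoding them is the canonical marker for PHA-accumulating
bacteria. Because *phaC* sequences diverge strongly across taxa, a
single concrete primer pair cannot amplify a class across genera;
instead one uses *degenerate* primers, written over the 15-letter IUPAC
alphabet, that are physically mixtures of all their concrete
realisations. `phascreen` implements the full computational chain for
such an assay: the algebra of ambiguity codes, mismatch-tolerant
matching and coverage, primer design under a degeneracy cap,
thermodynamic QC, in silico PCR, and panel-based class assignment.

## IUPAC algebra

Every position of a degenerate sequence denotes a set of one to four
bases; the degeneracy is the product of the set sizes and equals the
cardinality of the expansion set, a property the test suite checks
exhaustively. Reverse complementation maps each code to the code of the
complemented set and is an involution. Sequences are DNA only (`U` is
rejected) and gap characters are refused: alignment-derived strings
must be de-gapped by the caller, which keeps coordinate bookkeeping
unambiguous.

```{r}
degeneracy("CTKRTYAAYMRNCCVTAYATC")
revcomp("GAYTGGGG")
```

Expansion refuses to enumerate beyond an explicit limit so that a
mistyped `N`-rich primer cannot exhaust memory.

## Matching under an end-partitioned mismatch budget

A primer-template comparison is ungapped and positional: template base
`b` at primer position `i` is a mismatch iff `b` is not in the
position's code set. Degenerate compatibility is therefore never
penalised. The admission rule partitions the primer into a 5' and a 3'
region and caps mismatches per region and in total; the shipped default
is at most one mismatch in each end region and at most two overall,
which reflects how annealing tolerates early (5') wobble far better
than 3' disruption near the extension point.

Three choices here were genuinely open and are fixed as follows:

* **Region boundary.** Nothing in common usage pins where the "5' end"
  stops; the default boundary is `floor(L/2)` (the 5' region is the
  first half), the least surprising symmetric reading, and
  `mismatch_rule(split_index =)` overrides it for sensitivity analyses.
* **Template `N`.** Real contigs contain `N`; by default it counts as
  a mismatch (conservative -- an unknown base is not evidence of
  binding), with `n_policy = "wildcard"` available. Templates more than
  10% `N` trigger a warning.
* **Strand bookkeeping.** Forward primers are matched on the plus
  strand; reverse primers anneal to the minus strand, i.e. their
  reverse complement is sought on the plus strand, with the mismatch
  regions mapped accordingly (the primer's 3' terminus sits at the
  *left* edge of the plus-strand window). All sites are reported in
  plus-strand, 0-based half-open coordinates.

Coverage of a library is the fraction of records with at least one
admissible site; pair coverage additionally demands an
orientation-consistent pair (forward footprint entirely upstream of the
reverse footprint). Single-primer and pair coverage are deliberately
both exposed: summary statistics like an "accumulated" percentage over
a pair are ambiguous between the two, so the package never collapses
them. The matcher is validated against a brute-force oracle that
expands the primer and takes the best realisation per window, and obeys
two monotonicity laws checked as properties: relaxing any budget cap
never loses records, and enlarging any code set never loses records.

## Designing degenerate primers

The design task is the classic degenerate-primer-design problem:
maximise library coverage with a primer of bounded degeneracy. The
package uses a deterministic two-phase greedy in the spirit of the
established expansion/contraction heuristics for this problem, fully
specified so results are reproducible without any external binary:

* **Expansion** starts from a concrete seed window (degeneracy 1) and
  repeatedly applies the single (position, nucleotide) code enlargement
  with the best coverage gain, while the cap holds and the gain is
  positive. Ties: smaller resulting degeneracy, then leftmost position,
  then alphabetical base.
* **Contraction** aligns the seed to each record's best-matching window
  (minimal mismatches, leftmost tie-break), takes the position-wise
  union of the aligned bases, and greedily deletes the nucleotide whose
  loss costs fewest covered records (ties: rightmost position, then
  alphabetical) until the cap holds.

Both phases score coverage with the same mismatch rule as final
reporting -- one matching semantics throughout -- and every tie-break
is a total order, so design is a pure function of its inputs. Seed
windows are drawn from fractional gene regions (defaults: forward
candidates from the first half, reverse from the second, mirroring the
usual geometry of a screening amplicon); when a region yields more
windows than `max_seeds`, a deterministic stride subsample is used
rather than a random one, so no RNG is involved. Candidate pairs are
admissible when at least one record yields an orientation-consistent
product inside the size window, and are ranked by pair coverage, then
summed degeneracy.

The greedy evaluates thousands of single-code edits; internally an
incremental engine caches per-window mismatch counts and recomputes
only the edited primer position, rechecking only records whose covered
status can change. Its results are identical to the public matcher
(the reported coverage of every designed primer is recomputed through
`coverage()`).

## Thermodynamic QC

* **GC content** of a degenerate oligo is the expectation under uniform
  expansion choice -- per position, the fraction of the code set that
  is G or C -- which reduces to the exact count for concrete oligos.
* **Wallace Tm** is `2(A+T) + 4(G+C)` on expected base counts.
* **Nearest-neighbor Tm** uses the unified DNA parameter set
  (SantaLucia's 1998 compilation) with the entropic monovalent-salt
  correction `0.368 (L-1) ln[Na+]` and
  `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15`, at a documented default
  condition of 250 nM total oligo and 50 mM Na+. A degenerate oligo is
  a mixture with no single Tm, so the report carries min/mean/max over
  expansions -- exhaustively up to a degeneracy cap of 64, above it a
  seeded sample of 100 realisations.
* **Annealing scores** count complement-compatible code pairs over all
  ungapped offsets of one oligo against the reverse of the other (no
  gap penalties, matching the simple duplex scans oligo-analysis tools
  perform); the 3'-anchored variant restricts to offsets pairing the
  oligo's 3'-terminal base, the configuration that primes unwanted
  extension. A hairpin flag fires on any self-complementary stem of a
  configurable minimum length (default 4 bp) closing a loop of at
  least 3 nt.

Recommendations are deliberately coarse: no violation `ok`, one
`caution`, two or more `reject`, with a pair Tm difference above
threshold (default 5 degrees C) downgrading both primers one step.
Printed Tm columns in vendor tools and typeset tables are treated as
informative only -- their models and conditions are rarely stated -- so
none of them serve as test oracles; the Tm implementation is instead
checked against independently computed reference values under matched
conditions and closed-form cases.

## In silico PCR

Products are all orientation-consistent site pairs -- one primer's
plus-strand site entirely upstream of the other's minus-strand site --
in *both* template orientations, since a target gene may sit on either
strand of a contig; amplicon lengths are therefore invariant under
reverse-complementing the template, a property the suite asserts.
Product length spans both primer footprints (the length a band runs at
on a gel). Numerical defaults, each a knob:

* absolute size window 50-3000 bp (outside it, products are not
  reportable bands);
* expected-size tolerance +-20% for the `size_ok` ("specific") call --
  bands are matched to expected size by eye on a gel, so a tolerance is
  mandatory and 20% is the shipped, documented default, not a measured
  value;
* a mismatch at a primer's 3'-terminal position vetoes the site even
  when within budget (polymerases do not extend a mispaired 3'
  terminus). The veto is on by default for PCR simulation, off for
  coverage-style counting, and toggleable in both.

Non-specific products (wrong-size bands, the hallmark artefact of
highly degenerate primers) are partitioned out but always retained for
reporting, never dropped.

## Panel screening and class calls

The shipped panel is the four-pair *phaC* set: class I
(`ATCAAYAAGTAYTACATYCTT`/`TCCAGWASARCAKRTC`, 558 bp, Ta 44), class II
(`CTGGATGCGCCCCAACGATC`/`SAYCGGCGTRCCRCACA`, 203 bp, Ta 58), class III
(`GAHCATATTTCTAGCACAGACC`/`CCARTCNADCABRTAC`, 708 bp, Ta 46) and a
combined class III & IV pair
(`GTGTAYNTGYTDGAYTGGGG`/`GGRATRTTKCCVARYGTATC`, 352 bp, Ta 50).
Annealing temperatures are metadata: the in silico machinery never uses
them.

Classes I, II and III are called by their dedicated pairs; a class is
"+" only when at least one specific (expected-size) amplicon supports
it, an invariant asserted on every run. The panel has no IV-only pair,
so class IV is *inferred*: the III/IV pair specific while the class III
pair is silent. A positive III/IV signal next to a positive class III
signal reinforces III and does not create a IV call -- the only
consistent reading of a panel with separate III and IV report columns
but no IV-only chemistry -- and inferred IV calls are flagged as such.
Consequently an organism carrying both a class III and a class IV gene
is reported as III only; this masking is a documented limit of the
panel design, not of the software. Calls are per organism with
any-contig semantics, and the screen is strictly "panel amplification
predicted", never "PHA producer": biological interpretation stays with
the user.

## Synthetic ground truth

The generator emulates what the real assay sees -- gene families
sharing conserved degenerate motifs, and isolate genomes carrying class
loci -- while keeping exact truth:

* `make_library()` plants one forward-motif realisation and the
  reverse complement of a reverse-motif realisation per record at an
  exact product spacing, inside i.i.d. background of stated GC content
  (default 0.5), and injects requested numbers of mismatches into each
  primer-end region by flipping a planted base to one *outside* the
  code set. Injection avoids the 3'-terminal base by default so
  fixtures stay viable under the terminal veto (overridable to test the
  veto itself). The expected number of chance background windows
  matching a motif exactly is reported with the truth, so tests can
  size backgrounds to keep spurious sites negligible.
* `make_organism()` builds one contig with non-overlapping loci (at
  least 50 bp apart) for each requested class at the corresponding
  pair's expected product size; class IV is planted via the III/IV pair
  with no class III locus, matching how the panel can only infer IV.

Both are bit-reproducible from their seed and restore the caller's RNG
state. What they do *not* emulate -- and what passing tests therefore
do not establish about real data -- is phylogenetic correlation between
records, indels between primer sites, codon structure, GC skew along
the gene, and sequencing artefacts beyond uniform `N`.

## Problem sizes and numerical choices in the shipped checks

The test suite runs entirely on generated data at sizes chosen to
exercise every code path with exact expectations: libraries of 5-10
records of a few hundred bp, 6 kb single-contig organisms, 50 screened
organisms with randomly drawn class subsets (excluding the
unrecoverable III+IV combination), 500 random matcher instances checked
against the expansion oracle, 1000 random degeneracy/expansion
identities up to degeneracy 4096, and 100 seeded coverage-vs-truth
configurations. Design checks use capped seed counts (4-12) and short
genes so the greedy remains a few-second computation. The external
reference quantities recomputed by `scripts/acceptance.R` are the
degeneracies of the two most degenerate panel primers, phaCF4 (1536)
and phaCR4 (1728), which are pure IUPAC arithmetic.

## Known limitations

* No indel tolerance in matching: degenerate primer annealing is
  modelled positionally, so a single insertion between primer sites
  shifts products but a bulge inside a footprint is simply a chain of
  mismatches.
* No free-energy secondary-structure model: the hairpin and annealing
  checks are combinatorial counts, not ΔG folding.
* The design heuristic is greedy; it is deterministic and fast but
  carries no optimality guarantee for the underlying (NP-hard)
  coverage problem.
* Melting temperatures of degenerate mixtures are summarised over
  expansions under uniform weighting, which ignores synthesis-ratio
  biases in real oligo pools.
* Circular templates are unsupported; all inputs are treated as linear
  contigs or genes.
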