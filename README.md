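# phascreen

Degenerate-primer screening machinery for the four classes of
polyhydroxyalkanoate (PHA) synthase (*phaC*) genes.

PHA-accumulating bacteria are found by PCR with degenerate primers: an
oligo written over the 15-letter IUPAC alphabet (R = A/G, Y = C/T, ...,
N = A/C/G/T) is physically a mixture of all of its concrete
realisations, and a well-chosen mixture amplifies a whole gene family.
`phascreen` implements the computational side of such an assay for
microbiologists and bioinformaticians building or auditing *phaC*
screens:

* **IUPAC algebra** — degeneracy (the number of concrete oligos a
  degenerate primer denotes, `d(p) = prod_i |S_i|` for per-position
  code sets `S_i`), exhaustive expansion, reverse complement.
* **Mismatch-tolerant matching and coverage** — a primer matches a
  template window under an *end-partitioned* mismatch budget: at most
  `m5` mismatches in the primer's 5' region, `m3` in its 3' region and
  `mt` in total (default 1/1/2, boundary at `floor(L/2)`). Coverage of
  a library is the fraction of records with at least one admissible
  site.
* **Degenerate primer design** — a deterministic two-phase greedy
  heuristic for the classic degenerate-primer-design problem: maximise
  coverage subject to a degeneracy cap, by expansion of concrete seed
  windows and contraction of position-wise union codes, then pairing of
  forward/reverse candidates under product-size constraints.
* **Thermodynamic QC** — GC content, Wallace (`2(A+T) + 4(G+C)`) and
  unified nearest-neighbor melting temperatures (a degenerate oligo is
  a mixture, so Tm is reported as min/mean/max over expansions),
  self- and 3'-annealing scores, hairpin flag, pair recommendations.
* **In silico PCR and panel screening** — orientation-consistent
  forward/reverse site pairing with product-size windows, expected-size
  ("gel band") classification, non-specific product flagging, and a
  shipped four-pair *phaC* panel (classes I, II, III and a combined
  III/IV pair; class IV is inferred when the III/IV pair fires while
  the class III pair is silent).
* **Synthetic ground truth** — generators that plant primer-binding
  sites at known coordinates with controlled per-end mismatches, so
  every statistic above can be tested against exact truth.

## Worked example

```r
library(phascreen)

degeneracy("CTKRTYAAYMRNCCVTAYATC")
#> [1] 1536

phac_panel()[[4]]
#> <primer_pair phaCF8/phaCR8 [class III/IV]: GTGTAYNTGYTDGAYTGGGG / GGRATRTTKCCVARYGTATC, 352 bp, Ta 50 C>

# a synthetic isolate carrying a class I gene and a class IV gene
org <- make_organism(c("I", "IV"), seed = 42, organism_id = "isolate7")
screen_panel(org$library)
#> <screening_set: 1 organism(s)>
#>  organism_id I II III IV n_specific n_nonspecific inferred_iv
#>     isolate7 +  -   -  +          2             0        TRUE

simulate_pcr(phac_panel()[[1]], org$library$sequence[1],
             template_id = "isolate7")[, c("pair_id", "strand", "start",
                                           "end", "length", "size_ok")]
#>         pair_id strand start  end length size_ok
#> 1 phaCF1/phaCR1      +  1304 1862    558    TRUE
```

The screen matrix reads like a gel scored against expected band sizes:
the class I pair produced a 558 bp product (its expected size, so
`size_ok`), the III/IV pair produced its 352 bp product with the class
III pair silent, so class IV is called by inference (`inferred_iv`).
Coverage against a library with planted sites recovers the planted
truth:

```r
sim <- make_library("GTGTAYNTGYTDGAYTGGGG", "GGRATRTTKCCVARYGTATC",
                    n = 10, spacing = 352, seed = 1)
coverage("GTGTAYNTGYTDGAYTGGGG", sim$library, mismatch_rule(1, 1, 2),
         primer_id = "phaCF8")
#> <coverage_report phaCF8 (forward): 10/10 = 100.0%>
```

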