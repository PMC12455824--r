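zero_rule <- mismatch_rule(0, 0, 0)

toy_cfg <- function(...) {
  design_config(primer_length = 10, rule = zero_rule,
                fwd_region = c(0, 1), max_seeds = 50, ...)
}

test_that("seed enumeration slides, deduplicates and respects regions", {
  cfg <- toy_cfg()
  lib1 <- seq_library("a", "ACGTACGTAC")
  expect_identical(enumerate_seeds(lib1, cfg), "ACGTACGTAC")
  lib2 <- seq_library("a", "ACGTACGTACGT")  # L + 2 -> 3 windows
  expect_length(enumerate_seeds(lib2, cfg), 3L)
  lib3 <- seq_library(c("a", "b"), rep("ACGTACGTACGT", 2))
  expect_identical(enumerate_seeds(lib3, cfg), enumerate_seeds(lib2, cfg))
  expect_warning(
    enumerate_seeds(seq_library(c("a", "b"), c("ACGTACGTACGT", "ACGT")), cfg),
    "shorter than the primer length"
  )
  # windows containing N are not seeds
  expect_length(
    enumerate_seeds(seq_library("a", "ACGTNACGTACGTAC"), cfg), 1L
  )
})

test_that("expansion keeps a perfect seed and fixes single-position variation", {
  seed <- "ACGTACGTACGTACGTACGT"
  cfg <- design_config(primer_length = 20, max_degeneracy = 8,
                       rule = zero_rule, max_seeds = 10)
  ident <- seq_library(paste0("r", 1:4),
                       rep(paste0("TTTT", seed, "TTTT"), 4))
  d <- expand_seed(seed, ident, cfg)
  expect_identical(d$sequence, seed)      # no gain available
  expect_equal(d$degeneracy, 1)
  expect_equal(d$coverage$matched, 4L)
  # two variants differing at one primer position -> one 2-fold code
  variant <- seed
  substr(variant, 9, 9) <- "T"
  lib2 <- seq_library(c("a", "b"),
                      paste0("TTTT", c(seed, variant), "TTTT"))
  d2 <- expand_seed(seed, lib2, cfg)
  expect_equal(d2$coverage$matched, 2L)
  expect_equal(d2$degeneracy, 2)
  expect_identical(d2$sequence, "ACGTACGTWCGTACGTACGT")
  # cap 1 forbids the enlargement: only the seed's own variant is covered
  d3 <- expand_seed(seed, lib2,
                    design_config(primer_length = 20, max_degeneracy = 1,
                                  rule = zero_rule))
  expect_equal(d3$coverage$matched, 1L)
  expect_equal(d3$degeneracy, 1)
})

test_that("contraction keeps the union under the cap and sheds the minority", {
  seed <- "ACGTACGTACGTACGTACGT"
  wrap <- function(s) paste0("TTTT", s, "TTTT")
  ident <- seq_library(paste0("r", 1:3), rep(wrap(seed), 3))
  cfg <- design_config(primer_length = 20, max_degeneracy = 4,
                       rule = zero_rule)
  d <- contract_union(seed, ident, cfg)
  expect_identical(d$sequence, seed)
  expect_equal(d$coverage$matched, 3L)
  # majority variant (2 records) vs minority differing at 3 positions
  minority <- seed
  substr(minority, 2, 2) <- "G"
  substr(minority, 10, 10) <- "A"
  substr(minority, 18, 18) <- "A"
  lib <- seq_library(c("m1", "m2", "x"),
                     c(wrap(seed), wrap(seed), wrap(minority)))
  # cap above the union degeneracy (2^3): full coverage
  d_loose <- contract_union(seed, lib,
                            design_config(primer_length = 20,
                                          max_degeneracy = 8,
                                          rule = zero_rule))
  expect_equal(d_loose$coverage$matched, 3L)
  # cap 1 forces a concrete primer: the majority survives
  d_tight <- contract_union(seed, lib,
                            design_config(primer_length = 20,
                                          max_degeneracy = 1,
                                          rule = zero_rule))
  expect_equal(d_tight$degeneracy, 1)
  expect_equal(d_tight$coverage$matched, 2L)
  expect_identical(d_tight$sequence, seed)
})

test_that("designed primers always respect the cap and never undercut the seed", {
  set.seed(505)
  for (i in 1:6) {
    lib <- seq_library(paste0("r", 1:4),
                       vapply(1:4, function(j) rand_dna(60), character(1)))
    cfg <- design_config(primer_length = 12, max_degeneracy = 16,
                         rule = mismatch_rule(1, 1, 2))
    seed <- substr(lib$sequence[1], 11, 22)
    d <- expand_seed(seed, lib, cfg)
    expect_lte(d$degeneracy, 16)
    expect_gte(
      d$coverage$matched,
      coverage(seed, lib, cfg$rule)$matched
    )
    dc <- contract_union(seed, lib, cfg)
    expect_lte(dc$degeneracy, 16)
  }
})

test_that("pair design recovers planted motifs with the planted spacing", {
  sim <- make_library("GAYTGGGGAYTGGGGATYAC", "CCARTCGGATCCABRTACAC",
                      n = 5, spacing = 160, flank = 0, seed = 21)
  cfg <- design_config(
    primer_length = 20, max_degeneracy = 64,
    fwd_region = c(0, 0.2), rev_region = c(0.8, 1),
    max_seeds = 6, candidates_kept = 3,
    product_size_window = c(100, 300)
  )
  res <- design_pairs(sim$library, cfg)
  expect_gt(nrow(res), 0)
  expect_equal(res$pair_matched[1], 5L)
  expect_equal(res$expected_bp[1], 160)
  expect_true(all(res$fwd_degeneracy <= 64 & res$rev_degeneracy <= 64))
  # identical inputs give identical output (deterministic tie-breaks)
  expect_identical(design_pairs(sim$library, cfg), res)
  # a window excluding the planted spacing admits no pair
  cfg2 <- cfg
  cfg2$product_size_window <- c(300, 400)
  res2 <- design_pairs(sim$library, cfg2)
  expect_equal(nrow(res2), 0L)
  expect_match(attr(res2, "diagnostic"), "no")
})

test_that("an identical library yields a degeneracy-1 top pair covering all", {
  set.seed(9)
  gene <- rand_dna(140)
  lib <- seq_library(paste0("r", 1:4), rep(gene, 4))
  cfg <- design_config(primer_length = 16, max_degeneracy = 8,
                       max_seeds = 4, candidates_kept = 2,
                       product_size_window = c(60, 140))
  res <- design_pairs(lib, cfg)
  expect_gt(nrow(res), 0)
  expect_equal(res$fwd_degeneracy[1], 1)
  expect_equal(res$rev_degeneracy[1], 1)
  expect_equal(res$pair_matched[1], 4L)
  expect_equal(res$total[1], 4L)
})
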