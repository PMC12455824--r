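zero_rule <- mismatch_rule(0, 0, 0)

test_that("exact and degenerate-compatible windows are found", {
  s <- match_sites("ACGT", "TTACGTTT", zero_rule)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 6L)
  expect_equal(s$mismatch_total, 0L)
  # degenerate compatibility is not a mismatch
  s2 <- match_sites("AYGT", "TTACGTTT", zero_rule)
  expect_equal(s2$start, 2L)
  expect_equal(s2$mismatch_total, 0L)
  expect_equal(nrow(match_sites("ACGT", "TTTTTTTT")), 0L)
  # primer longer than template: empty, not an error
  expect_equal(nrow(match_sites("ACGTACGT", "ACG")), 0L)
})

test_that("minus-strand sites are reported in plus-strand coordinates", {
  # plant revcomp of a realisation of the primer
  primer <- "AYGTAAGG"
  planted <- oracle_revcomp("ACGTAAGG")
  template <- paste0("TTTT", planted, "TTTT")
  s <- match_sites(primer, template, zero_rule, strand = "minus")
  expect_equal(s$start, 4L)
  expect_equal(s$strand, "-")
  expect_equal(nrow(match_sites(primer, template, zero_rule,
                                strand = "plus")), 0L)
})

test_that("the end-partitioned budget is applied per region", {
  # primer length 8, split 4: one mismatch allowed in each half
  primer <- "ACGTACGT"
  t_5mm <- "TGGTACGT"  # 2 mismatches in the 5' half
  t_split <- "TCGTACGA" # 1 in each half
  expect_equal(nrow(match_sites(primer, t_5mm, mismatch_rule(1, 1, 2))), 0L)
  s <- match_sites(primer, t_split, mismatch_rule(1, 1, 2))
  expect_equal(s$mismatch_5, 1L)
  expect_equal(s$mismatch_3, 1L)
  # total cap is independent of the per-end caps
  expect_equal(nrow(match_sites(primer, t_split, mismatch_rule(1, 1, 1))), 0L)
  # moving the split reassigns the regions
  s2 <- match_sites(primer, t_5mm, mismatch_rule(2, 0, 2, split_index = 2))
  expect_equal(s2$mismatch_5, 2L)
})

test_that("matching agrees with the expansion brute-force oracle", {
  set.seed(101)
  for (i in 1:120) {
    L <- sample(6:10, 1)
    primer <- rand_degen(L, 64)
    template <- rand_dna(40)
    rule <- mismatch_rule(sample(0:2, 1), sample(0:2, 1), sample(0:3, 1))
    for (strand in c("plus", "minus")) {
      got <- match_sites(primer, template, rule, strand = strand)
      expect_identical(
        got$start,
        oracle_starts(primer, template, rule, strand),
        info = sprintf("i=%d strand=%s primer=%s", i, strand, primer)
      )
    }
  }
})

test_that("matched count is monotone in budget and in code enlargement", {
  set.seed(202)
  for (i in 1:25) {
    primer <- rand_degen(8, 16)
    lib <- seq_library(paste0("r", 1:6),
                       vapply(1:6, function(j) rand_dna(60), character(1)))
    base_rule <- mismatch_rule(1, 1, 2)
    m0 <- coverage(primer, lib, base_rule)$matched
    # relaxing any cap never loses records
    expect_gte(coverage(primer, lib, mismatch_rule(2, 1, 2))$matched, m0)
    expect_gte(coverage(primer, lib, mismatch_rule(1, 2, 2))$matched, m0)
    expect_gte(coverage(primer, lib, mismatch_rule(1, 1, 3))$matched, m0)
    # replacing one code by a superset never loses records
    p <- strsplit(primer, "")[[1]]
    pos <- sample(8, 1)
    p[pos] <- "N"
    expect_gte(coverage(paste(p, collapse = ""), lib, base_rule)$matched, m0)
  }
})

test_that("coverage equals revcomp coverage on reverse-complemented templates", {
  set.seed(303)
  for (i in 1:10) {
    primer <- rand_degen(10, 32)   # even length, symmetric caps
    seqs <- vapply(1:5, function(j) rand_dna(70), character(1))
    lib <- seq_library(paste0("r", 1:5), seqs)
    rclib <- seq_library(paste0("r", 1:5),
                         vapply(seqs, oracle_revcomp, character(1),
                                USE.NAMES = FALSE))
    rule <- mismatch_rule(1, 1, 2)
    expect_equal(
      coverage(primer, lib, rule)$matched,
      coverage(revcomp(primer), rclib, rule)$matched
    )
  }
})

test_that("template N is a mismatch by default and a wildcard on request", {
  s_mm <- match_sites("ACGT", "TTANGTTTTTTT", zero_rule)
  expect_equal(nrow(s_mm), 0L)
  s_wild <- match_sites("ACGT", "TTANGTTTTTTT", zero_rule,
                        n_policy = "wildcard")
  expect_equal(s_wild$start, 2L)
  expect_warning(
    match_sites("ACGT", "NNNNNNNNACGT", template_id = "noisy"),
    "noisy"
  )
})

test_that("coverage counts records with at least one admissible site", {
  lib <- seq_library(paste0("r", 1:3), rep(paste0("TT", "ACGT", "TT"), 3))
  rep1 <- coverage("ACGT", lib, zero_rule)
  expect_equal(rep1$matched, 3L)
  expect_equal(rep1$fraction, 1)
  expect_true(all(rep1$per_sequence$covered))
  # best site = fewest mismatches, then leftmost
  t2 <- paste0("AAGT", strrep("T", 10), "ACGT")
  rep2 <- coverage("ACGT", seq_library("x", t2), mismatch_rule(1, 1, 2))
  expect_equal(rep2$per_sequence$start, 14L)
  expect_equal(rep2$per_sequence$mismatch_total, 0L)
})

test_that("pair coverage requires an orientation-consistent site pair", {
  fwd <- "GAYTGGGGTTAC"
  rev <- "CCARTCGGATCC"
  both <- paste0(strrep("T", 10), "GACTGGGGTTAC", strrep("T", 30),
                 oracle_revcomp("CCAATCGGATCC"), strrep("T", 10))
  fwd_only <- paste0(strrep("T", 10), "GACTGGGGTTAC", strrep("T", 40))
  wrong_order <- paste0(strrep("T", 10), oracle_revcomp("CCAATCGGATCC"),
                        strrep("T", 30), "GACTGGGGTTAC", strrep("T", 10))
  lib <- seq_library(c("both", "fwd_only", "wrong_order"),
                     c(both, fwd_only, wrong_order))
  rep <- pair_coverage(fwd, rev, lib, zero_rule)
  expect_equal(rep$matched, 1L)
  expect_true(rep$per_sequence$covered[rep$per_sequence$id == "both"])
  expect_false(any(rep$per_sequence$covered[
    rep$per_sequence$id != "both"]))
})

test_that("pair coverage agrees with the brute-force pairing oracle", {
  set.seed(404)
  for (i in 1:15) {
    fwd <- rand_degen(7, 16)
    rev <- rand_degen(7, 16)
    seqs <- vapply(1:4, function(j) rand_dna(45), character(1))
    lib <- seq_library(paste0("r", 1:4), seqs)
    rule <- mismatch_rule(1, 1, 2)
    expect_equal(
      pair_coverage(fwd, rev, lib, rule)$matched,
      sum(vapply(seqs, oracle_pair_covered, logical(1),
                 fwd = fwd, rev = rev, rule = rule))
    )
  }
})
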