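test_that("GC content is exact for concrete sequences and an expectation for degenerate ones", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("CTGGATGCGCCCCAACGATC"), 65)  # 13 G/C of 20
  expect_equal(gc_content("S"), 100)
  expect_equal(gc_content("AY"), 25)  # A contributes 0, Y half
  set.seed(31)
  for (i in 1:20) {
    s <- rand_dna(sample(8:25, 1))
    chars <- strsplit(s, "")[[1]]
    expect_equal(gc_content(s),
                 100 * sum(chars %in% c("G", "C")) / length(chars))
  }
})

test_that("Wallace rule uses expected base counts", {
  expect_equal(tm_wallace("ACGT"), 12)
  expect_equal(tm_wallace("AATT"), 8)
  # degenerate: expected GC of AY is 0.5 -> 4*0.5 + 2*1.5
  expect_equal(tm_wallace("AY"), 5)
})

test_that("nearest-neighbor Tm matches independently computed reference values", {
  # frozen values from an independent implementation of the unified NN
  # model at the same conditions (250 nM total oligo, 50 mM Na+)
  ref <- c(
    ACGTACGTACGTACGTAA = 49.7012,
    CTGGATGCGCCCCAACGATC = 60.3166,
    ATCAATAAGTATTACATTCTT = 41.7013,
    GCGCGCGCGC = 53.4012
  )
  for (s in names(ref)) {
    expect_equal(unname(tm_nn(s)[["mean"]]), unname(ref[[s]]),
                 tolerance = 1e-4)
  }
})

test_that("degenerate Tm summarises the expansion mixture", {
  one <- tm_nn("ACGTACGTAC")
  expect_equal(one[["min"]], one[["max"]])
  expect_equal(one[["n"]], 1)
  mix <- tm_nn("AYGTRCGTACGT")
  exps <- expand_degenerate("AYGTRCGTACGT")
  tms <- vapply(exps, function(e) tm_nn(e)[["mean"]], numeric(1))
  expect_equal(mix[["min"]], min(tms))
  expect_equal(mix[["max"]], max(tms))
  expect_equal(mix[["mean"]], mean(tms))
  expect_true(mix[["min"]] <= mix[["mean"]] && mix[["mean"]] <= mix[["max"]])
  # sampling above the cap stays within seeded determinism
  big <- "CTKRTYAAYMRNCCVTAYATC"
  expect_identical(tm_nn(big, seed = 3), tm_nn(big, seed = 3))
  expect_equal(tm_nn(big)[["n"]], 100)
  expect_error(tm_nn("ACGT", oligo_conc = 0), "positive")
  expect_equal(melting_temperature("ACGT"), 12)
})

test_that("annealing scores count complement-compatible pairs", {
  sc <- annealing_scores("ACGT")
  expect_equal(sc[["max_anneal"]], 4)       # perfect palindrome
  expect_equal(sc[["max_3prime_anneal"]], 4)
  expect_equal(annealing_scores("AAAA")[["max_anneal"]], 0)
  set.seed(77)
  for (i in 1:20) {
    a <- rand_degen(sample(6:12, 1), 16)
    b <- rand_degen(sample(6:12, 1), 16)
    sa <- annealing_scores(a, b)
    expect_lte(sa[["max_3prime_anneal"]], sa[["max_anneal"]])
    expect_lte(sa[["max_anneal"]], min(nchar(a), nchar(b)))
    # the unanchored score is symmetric
    expect_equal(sa[["max_anneal"]], annealing_scores(b, a)[["max_anneal"]])
  }
})

test_that("hairpin detection finds a planted stem and spares a clean oligo", {
  rep_gggg <- oligo_qc("GGGGCAAATGCCCC")
  expect_true(rep_gggg$hairpin_flag)
  rep_clean <- oligo_qc("ACACACACACACAC")
  expect_false(rep_clean$hairpin_flag)
})

test_that("pair QC reports Tm difference and downgrades on violations", {
  q0 <- qc_pair("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA")
  expect_equal(q0$tm_difference, 0)
  # thresholds at infinity: always ok
  loose <- qc_thresholds(tm_diff_max = Inf, anneal3_max = Inf,
                         gc_min = -Inf, gc_max = Inf,
                         hairpin_stem_min = Inf)
  q1 <- qc_pair("GGGGCAAATGCCCC", "AAAAAAAATTTTTTTT", loose)
  expect_identical(unname(q1$recommendation), c("ok", "ok"))
  # a large Tm difference downgrades both by one step: ok -> caution
  q2 <- qc_pair("GCGCGCGCGCGCGCGCGC", "ATATATATATATATATAT",
                qc_thresholds(tm_diff_max = 5, anneal3_max = Inf,
                              gc_min = -Inf, gc_max = Inf,
                              hairpin_stem_min = Inf))
  expect_gt(q2$tm_difference, 5)
  expect_identical(unname(q2$recommendation), c("caution", "caution"))
})

test_that("oligo reports keep invariant bounds", {
  rep <- oligo_qc("GTGTAYNTGYTDGAYTGGGG")
  expect_true(rep$tm_nn_min <= rep$tm_nn_mean)
  expect_true(rep$tm_nn_mean <= rep$tm_nn_max)
  expect_true(rep$gc_percent >= 0 && rep$gc_percent <= 100)
  expect_lte(rep$max_self_anneal, nchar(rep$sequence))
  expect_true(rep$recommendation %in% c("ok", "caution", "reject"))
})
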