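fwd_motif <- "GAYTGGGGAYTGGGGATYAC"
rev_motif <- "CCARTCGGATCCABRTACAC"

test_that("planted sites are recovered exactly by the matcher", {
  sim <- make_library(fwd_motif, rev_motif, n = 8, spacing = 300, seed = 13)
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    rec <- sim$library[sim$library$id == tr$record_id, ]
    fs <- match_sites(fwd_motif, rec$sequence, mismatch_rule(0, 0, 0),
                      strand = "plus")
    rs <- match_sites(rev_motif, rec$sequence, mismatch_rule(0, 0, 0),
                      strand = "minus")
    expect_identical(fs$start, tr$fwd_start)
    expect_identical(rs$start, tr$rev_start)
    expect_equal(tr$rev_end - tr$fwd_start, 300L)
  }
  # the spurious-site expectation is reported and negligible here
  expect_lt(sum(attr(sim$truth, "expected_spurious")), 1e-6)
})

test_that("the generator is byte-identical under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(make_library(fwd_motif, rev_motif, n = 4, spacing = 250,
                           seed = 99)$library, f1)
  write_fasta(make_library(fwd_motif, rev_motif, n = 4, spacing = 250,
                           seed = 99)$library, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    make_library(fwd_motif, rev_motif, n = 4, spacing = 250,
                 seed = 100)$library$sequence,
    read_fasta(f1)$sequence
  ))
})

test_that("injected mismatches break coverage exactly as planned", {
  plan <- data.frame(
    fwd_5 = c(0, 1, 2, 0), fwd_3 = c(0, 1, 0, 2),
    rev_5 = 0, rev_3 = 0
  )
  sim <- make_library(fwd_motif, rev_motif, n = 4, spacing = 300,
                      mismatch_plan = plan, seed = 17)
  rep <- coverage(fwd_motif, sim$library, mismatch_rule(1, 1, 2))
  # records 1 and 2 are within budget; 3 (two 5' mm) and 4 (two 3' mm) not
  expect_identical(rep$per_sequence$covered, c(TRUE, TRUE, FALSE, FALSE))
  # the planted counts are visible in the matched sites
  expect_equal(rep$per_sequence$mismatch_5[2], 1L)
  expect_equal(rep$per_sequence$mismatch_3[2], 1L)
  # the reverse motif stayed clean
  expect_equal(coverage(rev_motif, sim$library, mismatch_rule(0, 0, 0),
                        orientation = "reverse")$matched, 4L)
})

test_that("zero-mismatch libraries are fully covered under any rule", {
  sim <- make_library(fwd_motif, rev_motif, n = 10, spacing = 280, seed = 23)
  expect_equal(coverage(fwd_motif, sim$library,
                        mismatch_rule(0, 0, 0))$matched, 10L)
  expect_equal(pair_coverage(fwd_motif, rev_motif, sim$library,
                             mismatch_rule(0, 0, 0))$matched, 10L)
})

test_that("impossible parameters are refused", {
  expect_error(
    make_library(fwd_motif, rev_motif, n = 2, spacing = 30),
    "spacing"
  )
  expect_error(
    make_library(fwd_motif, rev_motif, n = 1, spacing = 300,
                 mismatch_plan = data.frame(fwd_5 = 99, fwd_3 = 0,
                                            rev_5 = 0, rev_3 = 0)),
    "eligible"
  )
  expect_error(make_organism("I", genome_length = 100), "too small")
  expect_error(make_organism("V"), "I")
})

test_that("organism genomes carry each requested locus at the expected size", {
  org <- make_organism(c("I", "II", "III"), seed = 29, genome_length = 8000,
                       organism_id = "tri")
  expect_equal(nrow(org$truth), 3L)
  panel <- phac_panel()
  for (k in seq_len(nrow(org$truth))) {
    tr <- org$truth[k, ]
    pair <- panel[[which(vapply(panel, `[[`, character(1), "pair_id") ==
                           tr$pair_id)]]
    expect_equal(tr$product_length, pair$expected_bp)
    amps <- simulate_pcr(pair, org$library$sequence[1],
                         template_id = "tri")
    hit <- amps[amps$start == tr$fwd_start & amps$end == tr$rev_end, ]
    expect_equal(nrow(hit), 1L)
    expect_true(hit$size_ok)
  }
  # loci do not overlap
  o <- order(org$truth$fwd_start)
  expect_true(all(diff(cbind(org$truth$fwd_start,
                             org$truth$rev_end)[o, 1]) > 0))
  expect_true(all(org$truth$rev_end[o][-3] <= org$truth$fwd_start[o][-1]))
})
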