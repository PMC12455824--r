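# Synthetic fixtures with known ground truth: gene families sharing
# degenerate motifs at controlled spacing, organisms with planted
# panel-target loci, and controlled per-end mismatch injection. Stands
# in for downloaded gene libraries when exercising the matcher, the
# designer and the screen; every planted coordinate and injected
# mismatch is recorded so tests can compare against exact truth.

.random_background <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.sample_realisation <- function(sets) {
  vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1))
}

# inject `count` mismatches into realisation chars at primer-space
# positions drawn from `region`; a mismatch flips the base to one
# outside the motif's code set, so it scores as a mismatch for any
# realisation of the motif
.inject <- function(chars, sets, region, count, label) {
  if (count == 0L) return(chars)
  eligible <- region[vapply(sets[region], length, integer(1)) < 4L]
  if (count > length(eligible)) {
    stop(
      "cannot inject ", count, " mismatch(es) into the ", label,
      " region: only ", length(eligible), " eligible position(s)",
      call. = FALSE
    )
  }
  pos <- if (length(eligible) == 1L) eligible else
    sample(eligible, count)
  pos <- pos[seq_len(count)]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), sets[[p]])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

# primer-space 5'/3' region index sets under a rule
.end_regions <- function(L, rule, avoid_terminal) {
  split <- .resolve_split(rule, L)
  five <- 1L:split
  three <- (split + 1L):L
  if (avoid_terminal) three <- setdiff(three, L)
  list(five = five, three = three)
}

#' Generate a gene library with planted degenerate-motif sites
#'
#' Each record is i.i.d. random background DNA (at the stated GC
#' content) carrying one uniformly sampled realisation of the forward
#' motif and, downstream, the reverse complement of a realisation of
#' the reverse motif, spaced so the primer-to-primer product length
#' equals `spacing`. Controlled numbers of mismatches (bases outside
#' the motif's code set) are injected into the 5'/3' end regions of
#' each planted site. Fully reproducible from `seed`.
#'
#' @param motif_fwd,motif_rev degenerate motif strings (primer
#'   orientation, 5'->3').
#' @param n number of records.
#' @param spacing planted product length in bp (>= combined motif
#'   lengths).
#' @param background_gc GC fraction of the background.
#' @param mismatch_plan `NULL` (no mismatches) or a data.frame-like with
#'   columns `fwd_5`, `fwd_3`, `rev_5`, `rev_3`, recycled to `n` rows:
#'   mismatches to inject per record into each primer-end region.
#' @param rule [mismatch_rule()] defining the 5'/3' region boundary used
#'   for injection.
#' @param flank background length on each side of the planted span; the
#'   forward site start is drawn uniformly within the left flank.
#' @param avoid_terminal keep the primers' 3'-terminal position
#'   mismatch-free (default), so sites stay viable under a 3'-terminal
#'   veto; disable to test the veto itself.
#' @param seed RNG seed.
#' @param label library label.
#' @return List with `library` (a [seq_library()]) and `truth` (a
#'   `data.frame`: `record_id`, 0-based `fwd_start`, `fwd_end`,
#'   `rev_start`, `rev_end`, `product_length`, injected mismatch counts
#'   per primer end). Attribute `expected_spurious` on `truth` gives
#'   the expected number of additional exact-match windows arising by
#'   chance in the background, per motif.
#' @export
make_library <- function(motif_fwd, motif_rev, n = 10L, spacing,
                         background_gc = 0.5, mismatch_plan = NULL,
                         rule = mismatch_rule(), flank = 150L,
                         avoid_terminal = TRUE, seed = 1L,
                         label = "synthetic") {
  motif_fwd <- as_degenerate(motif_fwd, "motif_fwd")
  motif_rev <- as_degenerate(motif_rev, "motif_rev")
  Lf <- nchar(motif_fwd); Lr <- nchar(motif_rev)
  stopifnot(n >= 1, spacing >= Lf + Lr, background_gc > 0, background_gc < 1)
  spacing <- as.integer(spacing)
  flank <- as.integer(flank)
  n <- as.integer(n)
  plan <- if (is.null(mismatch_plan)) {
    data.frame(fwd_5 = 0L, fwd_3 = 0L, rev_5 = 0L, rev_3 = 0L)
  } else {
    as.data.frame(mismatch_plan)
  }
  stopifnot(all(c("fwd_5", "fwd_3", "rev_5", "rev_3") %in% names(plan)))
  plan <- plan[rep_len(seq_len(nrow(plan)), n), , drop = FALSE]
  fsets <- .seq_sets(motif_fwd)
  rsets <- .seq_sets(motif_rev)
  freg <- .end_regions(Lf, rule, avoid_terminal)
  rreg <- .end_regions(Lr, rule, avoid_terminal)
  .with_seed(seed, {
    seqs <- character(n)
    truth <- vector("list", n)
    for (k in seq_len(n)) {
      fw <- .inject(.inject(.sample_realisation(fsets), fsets,
                            freg$five, plan$fwd_5[k], "forward 5'"),
                    fsets, freg$three, plan$fwd_3[k], "forward 3'")
      rv <- .inject(.inject(.sample_realisation(rsets), rsets,
                            rreg$five, plan$rev_5[k], "reverse 5'"),
                    rsets, rreg$three, plan$rev_3[k], "reverse 3'")
      rv_planted <- revcomp(paste(rv, collapse = ""))
      total <- flank + spacing + flank
      bg <- strsplit(.random_background(total, background_gc), "",
                     fixed = TRUE)[[1]]
      fstart <- sample.int(flank + 1L, 1L)           # 1-based
      rend <- fstart + spacing - 1L                  # 1-based inclusive
      bg[fstart:(fstart + Lf - 1L)] <- fw
      bg[(rend - Lr + 1L):rend] <- strsplit(rv_planted, "", fixed = TRUE)[[1]]
      seqs[k] <- paste(bg, collapse = "")
      truth[[k]] <- data.frame(
        record_id = sprintf("rec%03d", k),
        fwd_start = fstart - 1L, fwd_end = fstart - 1L + Lf,
        rev_start = rend - Lr, rev_end = rend,
        product_length = spacing,
        fwd_mm5 = plan$fwd_5[k], fwd_mm3 = plan$fwd_3[k],
        rev_mm5 = plan$rev_5[k], rev_mm3 = plan$rev_3[k],
        stringsAsFactors = FALSE
      )
    }
    lib <- seq_library(sprintf("rec%03d", seq_len(n)), seqs, label = label)
    truth <- do.call(rbind, truth)
    # chance of background windows matching a motif exactly (per record,
    # zero-mismatch lower bound; mismatch budgets raise it)
    p_hit <- function(sets, len) {
      (nchar(seqs[1]) - len + 1L) * prod(lengths(sets) / 4)
    }
    attr(truth, "expected_spurious") <- c(
      fwd = p_hit(fsets, Lf), rev = p_hit(rsets, Lr)
    )
    list(library = lib, truth = truth)
  })
}

#' Generate a synthetic organism genome with planted panel targets
#'
#' Builds one random contig carrying, for each requested phaC class, a
#' non-overlapping target locus for the corresponding panel pair at
#' exactly the pair's expected product size: a realisation of the
#' forward primer at the locus start and the reverse complement of a
#' realisation of the reverse primer at its end. Class IV is planted
#' via the combined III/IV pair with no class III locus, matching how
#' the panel can only infer class IV.
#'
#' @param classes_present subset of `c("I", "II", "III", "IV")`; may be
#'   empty for a target-free genome.
#' @param panel a `phac_panel`; must contain pairs labelled `I`, `II`,
#'   `III` and `III/IV`.
#' @param genome_length contig length in bp; must fit all loci with
#'   at least 50 bp between them.
#' @param background_gc GC fraction of the background.
#' @param seed RNG seed.
#' @param organism_id id for the organism (and its contig).
#' @return List with `library` (single-contig [seq_library()] labelled
#'   `organism_id`) and `truth` (`data.frame`: `organism_id`, `class`,
#'   `pair_id`, 0-based `fwd_start`, `rev_end`, `product_length`).
#' @export
make_organism <- function(classes_present, panel = phac_panel(),
                          genome_length = 6000L, background_gc = 0.5,
                          seed = 1L, organism_id = "organism") {
  classes_present <- unique(as.character(classes_present))
  stopifnot(all(classes_present %in% c("I", "II", "III", "IV")))
  pair_class <- vapply(panel, `[[`, character(1), "class_label")
  pair_for <- function(cls) {
    want <- if (cls == "IV") "III/IV" else cls
    idx <- which(pair_class == want)
    if (!length(idx)) {
      stop("panel has no pair for class ", want, call. = FALSE)
    }
    panel[[idx[1]]]
  }
  classes_present <- sort(classes_present)
  pairs <- lapply(classes_present, pair_for)
  lens <- vapply(pairs, `[[`, integer(1), "expected_bp")
  k <- length(pairs)
  min_gap <- 50L
  if (genome_length < sum(lens) + (k + 1L) * min_gap) {
    stop(
      "genome_length ", genome_length, " too small for ", k,
      " locus/loci totalling ", sum(lens), " bp plus spacing",
      call. = FALSE
    )
  }
  .with_seed(seed, {
    bg <- strsplit(.random_background(genome_length, background_gc), "",
                   fixed = TRUE)[[1]]
    truth <- list()
    if (k > 0L) {
      slack <- genome_length - sum(lens) - (k + 1L) * min_gap
      cuts <- if (slack > 0) sort(sample.int(slack + 1L, k + 1L,
                                             replace = TRUE) - 1L)
              else rep(0L, k + 1L)
      extra <- diff(c(0L, cuts))
      extra <- c(extra, 0L)[seq_len(k + 1L)]
      pos <- min_gap + extra[1L]
      for (j in seq_len(k)) {
        pair <- pairs[[j]]
        fw <- .sample_realisation(.seq_sets(pair$fwd))
        rv <- revcomp(paste(
          .sample_realisation(.seq_sets(pair$rev)), collapse = ""
        ))
        start1 <- pos + 1L                       # 1-based locus start
        end1 <- pos + pair$expected_bp           # 1-based inclusive end
        bg[start1:(start1 + nchar(pair$fwd) - 1L)] <- fw
        bg[(end1 - nchar(pair$rev) + 1L):end1] <-
          strsplit(rv, "", fixed = TRUE)[[1]]
        truth[[j]] <- data.frame(
          organism_id = organism_id,
          class = classes_present[j],
          pair_id = pair$pair_id,
          fwd_start = start1 - 1L,
          rev_end = end1,
          product_length = pair$expected_bp,
          stringsAsFactors = FALSE
        )
        pos <- end1 + min_gap + extra[j + 1L]
      }
    }
    lib <- seq_library(organism_id, paste(bg, collapse = ""),
                       label = organism_id)
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      organism_id = character(), class = character(), pair_id = character(),
      fwd_start = integer(), rev_end = integer(),
      product_length = integer(), stringsAsFactors = FALSE
    )
    list(library = lib, truth = truth)
  })
}
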