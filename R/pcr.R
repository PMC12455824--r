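# In silico PCR: strand-aware site discovery, orientation-consistent
# pairing of forward/reverse sites, product-size filtering and
# expected-size classification.

.class_vocab <- c("I", "II", "III", "III/IV", "IV")

#' A labelled degenerate primer pair
#'
#' @param pair_id short identifier, e.g. `"phaCF1/phaCR1"`.
#' @param class_label targeted phaC synthase class: one of `"I"`, `"II"`,
#'   `"III"`, `"III/IV"`, `"IV"`.
#' @param fwd,rev degenerate primer strings, both written 5'->3'.
#' @param expected_bp expected amplicon size in bp (must exceed the
#'   combined primer footprints).
#' @param ta_c annealing temperature in degrees C (metadata only; the
#'   in silico machinery never uses it).
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(pair_id, class_label, fwd, rev, expected_bp,
                        ta_c = NA_real_) {
  if (!class_label %in% .class_vocab) {
    stop(
      "unknown class label '", class_label, "' for pair '", pair_id,
      "'; expected one of ", paste(.class_vocab, collapse = ", "),
      call. = FALSE
    )
  }
  fwd <- as_degenerate(fwd, "forward primer")
  rev <- as_degenerate(rev, "reverse primer")
  expected_bp <- as.integer(expected_bp)
  if (expected_bp <= nchar(fwd) + nchar(rev)) {
    stop(
      "expected amplicon (", expected_bp,
      " bp) must exceed the combined primer lengths",
      call. = FALSE
    )
  }
  structure(
    list(pair_id = pair_id, class_label = class_label, fwd = fwd, rev = rev,
         expected_bp = expected_bp, ta_c = ta_c),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(
    "<primer_pair ", x$pair_id, " [class ", x$class_label, "]: ",
    x$fwd, " / ", x$rev, ", ", x$expected_bp, " bp, Ta ",
    x$ta_c, " C>\n",
    sep = ""
  )
  invisible(x)
}

#' The shipped four-pair phaC screening panel
#'
#' The final panel used for phaC amplification: one pair each for class
#' I, class II and class III, plus a combined class III & IV pair.
#' Class IV has no dedicated pair; it is called by the III/IV pair in
#' the absence of a class III signal (see [screen_panel()]).
#'
#' @return A list of [primer_pair()] objects of class `phac_panel`.
#' @export
phac_panel <- function() {
  structure(
    list(
      primer_pair("phaCF1/phaCR1", "I",
                  "ATCAAYAAGTAYTACATYCTT", "TCCAGWASARCAKRTC", 558, 44),
      primer_pair("phaCF3/phaCR3", "II",
                  "CTGGATGCGCCCCAACGATC", "SAYCGGCGTRCCRCACA", 203, 58),
      primer_pair("phaCF5/phaCR5", "III",
                  "GAHCATATTTCTAGCACAGACC", "CCARTCNADCABRTAC", 708, 46),
      primer_pair("phaCF8/phaCR8", "III/IV",
                  "GTGTAYNTGYTDGAYTGGGG", "GGRATRTTKCCVARYGTATC", 352, 50)
    ),
    class = "phac_panel"
  )
}

#' @export
print.phac_panel <- function(x, ...) {
  cat("<phac_panel: ", length(x), " primer pair(s)>\n", sep = "")
  for (p in x) print(p)
  invisible(x)
}

#' Read a primer panel from a TSV file
#'
#' Expected columns: `pair_id`, `class`, `fwd`, `rev`, `expected_bp`,
#' `ta_c` (tab-separated, with header). The packaged default panel is at
#' `system.file("extdata", "phac_panel.tsv", package = "phascreen")`.
#'
#' @param path TSV file path.
#' @return A `phac_panel`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "class", "fwd", "rev", "expected_bp", "ta_c")
  if (!all(need %in% names(tab))) {
    stop("panel file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(
    lapply(seq_len(nrow(tab)), function(i) {
      primer_pair(tab$pair_id[i], tab$class[i], tab$fwd[i], tab$rev[i],
                  tab$expected_bp[i], tab$ta_c[i])
    }),
    class = "phac_panel"
  )
}

#' Write a primer panel to TSV
#'
#' @param panel a `phac_panel` or list of [primer_pair()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  tab <- data.frame(
    pair_id = vapply(panel, `[[`, character(1), "pair_id"),
    class = vapply(panel, `[[`, character(1), "class_label"),
    fwd = vapply(panel, `[[`, character(1), "fwd"),
    rev = vapply(panel, `[[`, character(1), "rev"),
    expected_bp = vapply(panel, `[[`, integer(1), "expected_bp"),
    ta_c = vapply(panel, function(p) as.numeric(p$ta_c), numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.empty_amplicons <- function() {
  data.frame(
    template_id = character(), pair_id = character(),
    class_label = character(), strand = character(),
    start = integer(), end = integer(),
    length = integer(), sequence = character(),
    fwd_mismatch_5 = integer(), fwd_mismatch_3 = integer(),
    rev_mismatch_5 = integer(), rev_mismatch_3 = integer(),
    size_ok = logical(), stringsAsFactors = FALSE
  )
}

# products of one template orientation: primer `up` anneals on the plus
# strand, primer `down` on the minus strand, `up` upstream of `down`
.orient_products <- function(up, down, template, rule, size_window,
                             veto_3prime, template_id, n_policy) {
  us <- match_sites(up, template, rule, strand = "plus",
                    template_id = template_id, n_policy = n_policy,
                    veto_3prime = veto_3prime)
  ds <- match_sites(down, template, rule, strand = "minus",
                    template_id = template_id, n_policy = n_policy,
                    veto_3prime = veto_3prime)
  if (nrow(us) == 0L || nrow(ds) == 0L) return(NULL)
  combos <- expand.grid(u = seq_len(nrow(us)), d = seq_len(nrow(ds)))
  len <- ds$end[combos$d] - us$start[combos$u]
  keep <- ds$start[combos$d] >= us$end[combos$u] &
    len >= size_window[1] & len <= size_window[2]
  if (!any(keep)) return(NULL)
  combos <- combos[keep, , drop = FALSE]
  list(us = us, ds = ds, combos = combos, len = len[keep])
}

#' Predict PCR products of a primer pair on a template
#'
#' Pairs every plus-strand site of one primer with every minus-strand
#' site of the other lying fully downstream of it, in both template
#' orientations (the target gene may sit on either strand of a contig),
#' and keeps products whose length -- 5' end of one primer footprint
#' through 5' end of the other, i.e. including both footprints, the
#' length a band runs at on a gel -- falls inside `size_window`. Each
#' amplicon carries `size_ok`, a comparison against the pair's expected
#' size within a fractional tolerance, and `strand` ("+" when the
#' forward primer annealed to the plus strand). Amplicon lengths are
#' invariant under reverse-complementing the template.
#'
#' By default a mismatch at a primer's 3'-terminal position vetoes the
#' site even when within budget, since polymerases do not extend a
#' mispaired 3' terminus; disable with `veto_3prime = FALSE`.
#'
#' @param pair a [primer_pair()].
#' @param template concrete template string, or a [seq_library()] record
#'   row; plain strings get `template_id`.
#' @param rule a [mismatch_rule()].
#' @param size_window absolute `(min, max)` product length kept, bp.
#' @param size_tolerance fractional tolerance for `size_ok`
#'   (default 0.2, i.e. within 20 percent of the expected size).
#' @param veto_3prime see above.
#' @param template_id id used when `template` is a plain string.
#' @param n_policy see [match_sites()].
#' @return `data.frame` of amplicons sorted by `start` then `length`:
#'   `template_id`, `pair_id`, `class_label`, `strand`, `start`, `end`
#'   (0-based half-open, plus-strand coordinates), `length`, `sequence`
#'   (written 5'->3' from the forward primer), per-primer 5'/3'
#'   mismatch counts and `size_ok`. Zero rows means no amplification.
#' @export
simulate_pcr <- function(pair, template, rule = mismatch_rule(),
                         size_window = c(50, 3000), size_tolerance = 0.2,
                         veto_3prime = TRUE, template_id = "template",
                         n_policy = c("mismatch", "wildcard")) {
  stopifnot(inherits(pair, "primer_pair"))
  n_policy <- match.arg(n_policy)
  if (inherits(template, "seq_library")) {
    stopifnot(nrow(template) == 1L)
    template_id <- template$id
    template <- template$sequence
  }
  template <- toupper(template)
  mk <- function(prod, strand) {
    if (is.null(prod)) return(NULL)
    start <- prod$us$start[prod$combos$u]
    end <- prod$ds$end[prod$combos$d]
    # per-primer mismatch columns always describe the pair's own
    # forward / reverse primer, whichever strand it annealed to
    if (strand == "+") {
      fmm <- prod$us[prod$combos$u, c("mismatch_5", "mismatch_3")]
      rmm <- prod$ds[prod$combos$d, c("mismatch_5", "mismatch_3")]
    } else {
      fmm <- prod$ds[prod$combos$d, c("mismatch_5", "mismatch_3")]
      rmm <- prod$us[prod$combos$u, c("mismatch_5", "mismatch_3")]
    }
    seqs <- substring(template, start + 1L, end)
    if (strand == "-") {
      seqs <- vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
    }
    data.frame(
      template_id = template_id,
      pair_id = pair$pair_id,
      class_label = pair$class_label,
      strand = strand,
      start = start, end = end, length = prod$len,
      sequence = seqs,
      fwd_mismatch_5 = fmm$mismatch_5, fwd_mismatch_3 = fmm$mismatch_3,
      rev_mismatch_5 = rmm$mismatch_5, rev_mismatch_3 = rmm$mismatch_3,
      size_ok = abs(prod$len - pair$expected_bp) <=
        size_tolerance * pair$expected_bp,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    mk(.orient_products(pair$fwd, pair$rev, template, rule, size_window,
                        veto_3prime, template_id, n_policy), "+"),
    mk(.orient_products(pair$rev, pair$fwd, template, rule, size_window,
                        veto_3prime, template_id, n_policy), "-")
  )
  if (is.null(out)) return(.empty_amplicons())
  out[order(out$start, out$length, out$strand), , drop = FALSE]
}

#' Partition amplicons into expected-size and non-specific products
#'
#' Mirrors reading a gel against the expected band: a product is
#' specific when its length is within `tolerance * expected_size` of the
#' expected size; everything else is a non-specific product, retained
#' for reporting rather than discarded.
#'
#' @param amplicons amplicon `data.frame` from [simulate_pcr()].
#' @param expected_size expected amplicon length, bp (> 0).
#' @param tolerance fractional tolerance (0 keeps only exact lengths).
#' @return List with elements `specific` and `nonspecific`.
#' @export
flag_nonspecific <- function(amplicons, expected_size, tolerance = 0.2) {
  stopifnot(expected_size > 0, tolerance >= 0)
  ok <- abs(amplicons$length - expected_size) <= tolerance * expected_size
  list(
    specific = amplicons[ok, , drop = FALSE],
    nonspecific = amplicons[!ok, , drop = FALSE]
  )
}
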