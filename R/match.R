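# Mismatch-tolerant matching of degenerate primers against concrete
# templates, under an end-partitioned mismatch budget: at most max_5prime
# mismatches in the 5' region of the primer, max_3prime in the 3' region,
# and max_total overall. A mismatch is a template base outside the primer
# code's base set; degenerate compatibility is never a mismatch.

#' Mismatch budget for primer-template matching
#'
#' The default budget allows a maximum of two mismatches, one in the
#' primer's 5' half and one in its 3' half. The boundary between the two
#' regions defaults to `floor(L/2)` for a primer of length `L` (the 5'
#' region is the first half); set `split_index` to move it. `max_total`
#' is an independent cap, not the sum of the per-end caps.
#'
#' @param max_5prime max mismatches in primer positions `[1, split]`.
#' @param max_3prime max mismatches in primer positions `(split, L]`.
#' @param max_total max mismatches overall.
#' @param split_index last primer position of the 5' region (1-based), or
#'   `NULL` for `floor(L/2)`.
#' @return An object of class `mismatch_rule`.
#' @export
mismatch_rule <- function(max_5prime = 1L, max_3prime = 1L, max_total = 2L,
                          split_index = NULL) {
  stopifnot(
    max_5prime >= 0, max_3prime >= 0, max_total >= 0,
    is.null(split_index) || (length(split_index) == 1L && split_index >= 1)
  )
  structure(
    list(
      max_5prime = as.integer(max_5prime),
      max_3prime = as.integer(max_3prime),
      max_total = as.integer(max_total),
      split_index = if (is.null(split_index)) NULL else as.integer(split_index)
    ),
    class = "mismatch_rule"
  )
}

#' @export
print.mismatch_rule <- function(x, ...) {
  cat(
    "<mismatch_rule: <=", x$max_5prime, "in 5' region, <=", x$max_3prime,
    "in 3' region, <=", x$max_total, "total, split =",
    if (is.null(x$split_index)) "floor(L/2)" else x$split_index, ">\n"
  )
  invisible(x)
}

# resolve the 5'/3' boundary for a primer of length L
.resolve_split <- function(rule, L) {
  s <- if (is.null(rule$split_index)) L %/% 2L else rule$split_index
  if (s < 1L || s > L - 1L) {
    stop(
      "split_index ", s, " outside [1, ", L - 1L, "] for primer length ", L,
      call. = FALSE
    )
  }
  s
}

# per-window mismatch matrix: mm[w, i] is TRUE when scan position i of the
# window starting at w disagrees with the scanned pattern. Template N is a
# mismatch unless n_wildcard.
.window_mismatches <- function(p_chars, tmpl_chars, n_wildcard) {
  L <- length(p_chars)
  nw <- length(tmpl_chars) - L + 1L
  if (nw < 1L) return(NULL)
  mm <- matrix(FALSE, nrow = nw, ncol = L)
  for (i in seq_len(L)) {
    s <- .iupac_sets[[p_chars[i]]]
    tm <- tmpl_chars[i:(i + nw - 1L)]
    m <- !(tm %in% s)
    if (n_wildcard) m[tm == "N"] <- FALSE
    mm[, i] <- m
  }
  mm
}

# scan one strand; returns a data.frame of admissible sites in plus-strand
# coordinates. On the minus strand the reverse complement of the primer is
# scanned, so window column j corresponds to primer position L+1-j: the
# primer's 5' region maps to the window's right end and its 3'-terminal
# base to the window's left end.
.scan_strand <- function(primer, tmpl_chars, rule, strand, n_wildcard,
                         veto_3prime) {
  L <- nchar(primer)
  split <- .resolve_split(rule, L)
  scanned <- if (strand == "+") primer else revcomp(primer)
  mm <- .window_mismatches(
    strsplit(scanned, "", fixed = TRUE)[[1]], tmpl_chars, n_wildcard
  )
  if (is.null(mm)) return(NULL)
  if (strand == "+") {
    cols5 <- seq_len(split)
    term <- L
  } else {
    cols5 <- (L - split + 1L):L
    term <- 1L
  }
  m5 <- rowSums(mm[, cols5, drop = FALSE])
  m3 <- rowSums(mm[, -cols5, drop = FALSE])
  ok <- m5 <= rule$max_5prime & m3 <= rule$max_3prime &
    (m5 + m3) <= rule$max_total
  if (veto_3prime) ok <- ok & !mm[, term]
  w <- which(ok)
  if (!length(w)) return(NULL)
  data.frame(
    strand = strand,
    start = w - 1L,           # 0-based inclusive
    end = w - 1L + L,         # 0-based exclusive
    mismatch_5 = as.integer(m5[w]),
    mismatch_3 = as.integer(m3[w]),
    mismatch_total = as.integer(m5[w] + m3[w]),
    stringsAsFactors = FALSE
  )
}

#' Find primer binding sites on a template
#'
#' Scans every window of the template for compatibility with the
#' degenerate primer under an end-partitioned [mismatch_rule()].
#' Alignment is ungapped and positional. Minus-strand sites (the primer
#' annealing to the reverse complement of the template) are reported in
#' plus-strand coordinates, 0-based half-open.
#'
#' @param primer degenerate primer string, 5'->3'.
#' @param template concrete template string (A/C/G/T/N).
#' @param rule a [mismatch_rule()].
#' @param strand `"plus"`, `"minus"`, or `"both"`.
#' @param template_id id carried into the result.
#' @param n_policy how a template `N` scores against the primer:
#'   `"mismatch"` (conservative default) or `"wildcard"`.
#' @param veto_3prime when `TRUE`, a mismatch at the primer's 3'-terminal
#'   position rejects the site regardless of budget (polymerases do not
#'   extend a mispaired 3' terminus). Off by default for coverage-style
#'   counting; [simulate_pcr()] turns it on.
#' @return `data.frame` with columns `template_id`, `strand`, `start`,
#'   `end`, `mismatch_5`, `mismatch_3`, `mismatch_total`, sorted by
#'   `start`. A primer longer than the template yields zero rows.
#' @examples
#' match_sites("AYGT", "TTACGTTT", mismatch_rule(0, 0, 0))
#' @export
match_sites <- function(primer, template, rule = mismatch_rule(),
                        strand = c("plus", "both", "minus"),
                        template_id = "template",
                        n_policy = c("mismatch", "wildcard"),
                        veto_3prime = FALSE) {
  primer <- as_degenerate(primer, what = "primer")
  strand <- match.arg(strand)
  n_policy <- match.arg(n_policy)
  stopifnot(inherits(rule, "mismatch_rule"))
  template <- toupper(template)
  tmpl_chars <- strsplit(template, "", fixed = TRUE)[[1]]
  n_frac <- mean(tmpl_chars == "N")
  if (n_frac > 0.1) {
    warning(
      "template '", template_id, "' is ", round(100 * n_frac), "% N",
      call. = FALSE
    )
  }
  strands <- switch(strand, plus = "+", minus = "-", both = c("+", "-"))
  out <- do.call(rbind, lapply(strands, function(s) {
    .scan_strand(primer, tmpl_chars, rule, s, n_policy == "wildcard",
                 veto_3prime)
  }))
  if (is.null(out)) {
    out <- data.frame(
      strand = character(), start = integer(), end = integer(),
      mismatch_5 = integer(), mismatch_3 = integer(),
      mismatch_total = integer(), stringsAsFactors = FALSE
    )
  }
  out <- cbind(
    data.frame(template_id = rep(template_id, nrow(out)),
               stringsAsFactors = FALSE),
    out
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

# best site: fewest total mismatches, then smallest start
.best_site <- function(sites) {
  if (nrow(sites) == 0L) return(NULL)
  sites[order(sites$mismatch_total, sites$start), , drop = FALSE][1L, , drop = FALSE]
}

#' Library coverage of a degenerate primer
#'
#' Counts how many records of a library carry at least one admissible
#' binding site. Forward primers are matched on the plus strand of each
#' record; reverse primers anneal to the minus strand, i.e. their reverse
#' complement is sought on the plus strand (`orientation = "reverse"`).
#'
#' @param primer degenerate primer string.
#' @param lib a [seq_library()].
#' @param rule a [mismatch_rule()].
#' @param orientation `"forward"` or `"reverse"`.
#' @param primer_id label carried into the report.
#' @param n_policy see [match_sites()].
#' @return An object of class `coverage_report`: a list with `primer_id`,
#'   `matched`, `total`, `fraction` and `per_sequence` (one row per
#'   record; site columns are `NA` for uncovered records, and the
#'   reported site is the best one -- fewest mismatches, then leftmost).
#' @export
coverage <- function(primer, lib, rule = mismatch_rule(),
                     orientation = c("forward", "reverse"),
                     primer_id = "primer",
                     n_policy = c("mismatch", "wildcard")) {
  orientation <- match.arg(orientation)
  n_policy <- match.arg(n_policy)
  stopifnot(inherits(lib, "seq_library"), nrow(lib) >= 1L)
  strand <- if (orientation == "forward") "plus" else "minus"
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    sites <- match_sites(
      primer, lib$sequence[i], rule, strand = strand,
      template_id = lib$id[i], n_policy = n_policy
    )
    best <- .best_site(sites)
    if (is.null(best)) {
      data.frame(
        id = lib$id[i], covered = FALSE, strand = NA_character_,
        start = NA_integer_, end = NA_integer_,
        mismatch_5 = NA_integer_, mismatch_3 = NA_integer_,
        mismatch_total = NA_integer_, stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        id = lib$id[i], covered = TRUE, strand = best$strand,
        start = best$start, end = best$end,
        mismatch_5 = best$mismatch_5, mismatch_3 = best$mismatch_3,
        mismatch_total = best$mismatch_total, stringsAsFactors = FALSE
      )
    }
  })
  per_sequence <- do.call(rbind, rows)
  structure(
    list(
      primer_id = primer_id,
      primer = as_degenerate(primer, "primer"),
      orientation = orientation,
      matched = sum(per_sequence$covered),
      total = nrow(lib),
      fraction = sum(per_sequence$covered) / nrow(lib),
      per_sequence = per_sequence
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(
    "<coverage_report ", x$primer_id, " (", x$orientation, "): ",
    x$matched, "/", x$total, " = ",
    sprintf("%.1f%%", 100 * x$fraction), ">\n",
    sep = ""
  )
  invisible(x)
}

#' Joint coverage of a forward/reverse primer pair
#'
#' A record counts as covered when the forward primer has a plus-strand
#' site, the reverse primer has a minus-strand site, and at least one
#' such pair is orientation-consistent: the forward footprint lies
#' entirely upstream of the reverse footprint on the plus strand.
#'
#' @param fwd,rev degenerate primer strings (both written 5'->3').
#' @inheritParams coverage
#' @return A `coverage_report`; `per_sequence` reports the best forward
#'   site of each covered record.
#' @export
pair_coverage <- function(fwd, rev, lib, rule = mismatch_rule(),
                          primer_id = "pair",
                          n_policy = c("mismatch", "wildcard")) {
  n_policy <- match.arg(n_policy)
  stopifnot(inherits(lib, "seq_library"), nrow(lib) >= 1L)
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    fs <- match_sites(fwd, lib$sequence[i], rule, strand = "plus",
                      template_id = lib$id[i], n_policy = n_policy)
    rs <- match_sites(rev, lib$sequence[i], rule, strand = "minus",
                      template_id = lib$id[i], n_policy = n_policy)
    ok_f <- NULL
    if (nrow(fs) && nrow(rs)) {
      consistent <- vapply(
        seq_len(nrow(fs)),
        function(j) any(rs$start >= fs$end[j]),
        logical(1)
      )
      if (any(consistent)) ok_f <- .best_site(fs[consistent, , drop = FALSE])
    }
    if (is.null(ok_f)) {
      data.frame(
        id = lib$id[i], covered = FALSE, strand = NA_character_,
        start = NA_integer_, end = NA_integer_,
        mismatch_5 = NA_integer_, mismatch_3 = NA_integer_,
        mismatch_total = NA_integer_, stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        id = lib$id[i], covered = TRUE, strand = ok_f$strand,
        start = ok_f$start, end = ok_f$end,
        mismatch_5 = ok_f$mismatch_5, mismatch_3 = ok_f$mismatch_3,
        mismatch_total = ok_f$mismatch_total, stringsAsFactors = FALSE
      )
    }
  })
  per_sequence <- do.call(rbind, rows)
  structure(
    list(
      primer_id = primer_id,
      primer = paste(as_degenerate(fwd, "fwd"), as_degenerate(rev, "rev"),
                     sep = "/"),
      orientation = "pair",
      matched = sum(per_sequence$covered),
      total = nrow(lib),
      fraction = sum(per_sequence$covered) / nrow(lib),
      per_sequence = per_sequence
    ),
    class = "coverage_report"
  )
}
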