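# Independent brute-force oracles and random-instance generators used
# across the suite. The oracles deliberately work by exhaustive
# expansion of the degenerate primer -- a different route than the
# package's positional code-set matcher -- so agreement is evidence,
# not tautology.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random degenerate sequence with degeneracy <= max_deg
rand_degen <- function(len, max_deg) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sizes <- nchar(Biostrings::IUPAC_CODE_MAP)
  deg <- 1
  out <- character(len)
  for (i in seq_len(len)) {
    ok <- codes[deg * sizes <= max_deg]
    out[i] <- sample(ok, 1L)
    deg <- deg * sizes[match(out[i], codes)]
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# expansion-based site oracle: window start positions (0-based) where
# some concrete expansion of the primer satisfies the end-partitioned
# rule. strand "minus": the primer anneals to the reverse complement of
# the window, so expansions are compared against revcomp(window) in
# primer coordinates. Template N counts as a mismatch.
oracle_starts <- function(primer, template, rule, strand = "plus") {
  L <- nchar(primer)
  split <- if (is.null(rule$split_index)) L %/% 2L else rule$split_index
  exps <- expand_degenerate(primer)
  emat <- do.call(rbind, strsplit(exps, "", fixed = TRUE))
  template <- toupper(template)
  n <- nchar(template)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in 1:(n - L + 1L)) {
    w <- substr(template, s, s + L - 1L)
    target <- if (strand == "plus") w else oracle_revcomp(w)
    wc <- strsplit(target, "", fixed = TRUE)[[1]]
    mm <- sweep(emat, 2, wc, FUN = "!=")
    m5 <- rowSums(mm[, 1:split, drop = FALSE])
    m3 <- rowSums(mm[, (split + 1L):L, drop = FALSE])
    if (any(m5 <= rule$max_5prime & m3 <= rule$max_3prime &
              (m5 + m3) <= rule$max_total)) {
      hits <- c(hits, s - 1L)
    }
  }
  hits
}

# brute-force pair coverage: a record counts iff some oracle forward
# site lies fully upstream of some oracle minus-strand site
oracle_pair_covered <- function(fwd, rev, sequence, rule) {
  fs <- oracle_starts(fwd, sequence, rule, "plus")
  rs <- oracle_starts(rev, sequence, rule, "minus")
  if (!length(fs) || !length(rs)) return(FALSE)
  any(outer(fs + nchar(fwd), rs, FUN = "<="))
}
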