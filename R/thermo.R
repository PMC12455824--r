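# Thermodynamic and self-complementarity QC for (degenerate) oligos:
# GC content, Wallace and nearest-neighbor melting temperatures,
# self/3'-annealing scores, hairpin flag, pair recommendation.
#
# A degenerate oligo is physically a mixture of its expansions, so
# nearest-neighbor Tm is summarised as min/mean/max over expansions
# (exhaustive up to a cap, seeded sampling above it).

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide step.
.nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

#' Expected GC content of a degenerate sequence
#'
#' For each position, the fraction of the position's code set that is G
#' or C; averaged over positions and scaled to percent. This is the
#' expected GC content under uniform choice of expansions, and reduces
#' to the exact GC percentage for a concrete sequence.
#'
#' @param seq degenerate DNA string.
#' @return GC content in percent (0-100).
#' @examples
#' gc_content("CTGGATGCGCCCCAACGATC") # 65
#' gc_content("S")                    # 100: S = G/C
#' @export
gc_content <- function(seq) {
  seq <- as_degenerate(seq)
  sets <- .seq_sets(seq)
  frac <- vapply(sets, function(s) mean(s %in% c("G", "C")), numeric(1))
  100 * mean(frac)
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` on expected base counts, in degrees Celsius.
#' For a degenerate sequence the expected G+C count is the sum of
#' per-position GC fractions, so the rule stays linear in the mixture.
#'
#' @param seq degenerate DNA string.
#' @return Tm in degrees C.
#' @examples
#' tm_wallace("ACGT") # 12
#' @export
tm_wallace <- function(seq) {
  seq <- as_degenerate(seq)
  L <- nchar(seq)
  gc_count <- gc_content(seq) / 100 * L
  4 * gc_count + 2 * (L - gc_count)
}

# nearest-neighbor Tm of a single concrete oligo (degrees C).
# Duplex with its exact complement, non-self-complementary assumption:
# Tm = 1000 dH / (dS + 0.368 (L-1) ln[Na+] + R ln(Ct/4)) - 273.15
.tm_nn_concrete <- function(chars, oligo_conc, na_conc) {
  L <- length(chars)
  steps <- paste0(chars[-L], chars[-1L])
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  for (term in chars[c(1L, L)]) {       # initiation with terminal pair
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (L - 1) * log(na_conc)
  1000 * dh / (ds + 1.987 * log(oligo_conc / 4)) - 273.15
}

#' Nearest-neighbor melting temperature of a degenerate oligo
#'
#' Uses the unified DNA nearest-neighbor parameter set with a
#' monovalent-salt entropy correction, at the stated total oligo and Na+
#' concentrations. A degenerate oligo is a mixture: Tm is computed per
#' concrete expansion and summarised as min/mean/max. All expansions are
#' used when the degeneracy is at most `sample_cap`; above that, a
#' seeded sample of `n_sample` expansions (uniform per position) is
#' drawn instead.
#'
#' @param seq degenerate DNA string (length >= 2).
#' @param oligo_conc total oligo concentration in mol/L (default 250 nM).
#' @param na_conc monovalent cation concentration in mol/L (default 50 mM).
#' @param sample_cap largest degeneracy expanded exhaustively.
#' @param n_sample sample size above the cap (>= 100 recommended).
#' @param seed RNG seed for the sample.
#' @return Named numeric vector `c(min, mean, max, n)`; `n` is the
#'   number of expansions evaluated.
#' @export
tm_nn <- function(seq, oligo_conc = 250e-9, na_conc = 50e-3,
                  sample_cap = 64, n_sample = 100, seed = 1) {
  seq <- as_degenerate(seq)
  if (oligo_conc <= 0 || na_conc <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (nchar(seq) < 2L) stop("need at least 2 bases for a duplex", call. = FALSE)
  d <- degeneracy(seq)
  if (d <= sample_cap) {
    mats <- strsplit(expand_degenerate(seq, limit = sample_cap), "",
                     fixed = TRUE)
  } else {
    sets <- .seq_sets(seq)
    mats <- .with_seed(seed, {
      replicate(
        n_sample,
        vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        simplify = FALSE
      )
    })
  }
  tms <- vapply(mats, .tm_nn_concrete, numeric(1),
                oligo_conc = oligo_conc, na_conc = na_conc)
  c(min = min(tms), mean = mean(tms), max = max(tms), n = length(tms))
}

#' Melting temperature of a (degenerate) oligo
#'
#' Dispatcher over the two implemented models: the Wallace rule
#' ([tm_wallace()]) and the nearest-neighbor model ([tm_nn()]).
#'
#' @param seq degenerate DNA string.
#' @param method `"wallace"` or `"nearest_neighbor"`.
#' @param ... passed to [tm_nn()].
#' @return Wallace: a single temperature. Nearest-neighbor: the
#'   min/mean/max summary of [tm_nn()].
#' @export
melting_temperature <- function(seq,
                                method = c("wallace", "nearest_neighbor"),
                                ...) {
  method <- match.arg(method)
  if (method == "wallace") tm_wallace(seq) else tm_nn(seq, ...)
}

# can code a (read on one strand) pair with code b (other strand)?
# TRUE iff some base of a's set is Watson-Crick complementary to some
# base of b's set, i.e. a's set intersects the complement of b's set.
.codes_can_pair <- local({
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- matrix(FALSE, 15L, 15L, dimnames = list(names(Biostrings::IUPAC_CODE_MAP),
                                               names(Biostrings::IUPAC_CODE_MAP)))
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  for (a in rownames(m)) {
    for (b in colnames(m)) {
      m[a, b] <- length(intersect(sets[[a]], unname(comp[sets[[b]]]))) > 0L
    }
  }
  m
})

#' Self/cross annealing scores of two oligos
#'
#' Slides `a` (5'->3') along the reverse of `b` at every ungapped offset
#' and counts, per offset, the aligned code pairs whose base sets admit
#' a Watson-Crick pairing. `max_anneal` is the maximum count over all
#' offsets; `max_3prime_anneal` restricts the maximum to offsets in
#' which `a`'s 3'-terminal base is paired (3'-anchored duplexes prime
#' extension, so they are the dangerous ones). With `b = a` these are
#' the classic self-annealing and 3'-self-annealing scores.
#'
#' @param a,b degenerate DNA strings (default `b = a`).
#' @return Named integer vector `c(max_anneal, max_3prime_anneal)`.
#' @examples
#' annealing_scores("ACGT")  # perfect palindrome: 4, 4
#' annealing_scores("AAAA")  # A cannot pair A: 0, 0
#' @export
annealing_scores <- function(a, b = a) {
  a <- as_degenerate(a, "a"); b <- as_degenerate(b, "b")
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  rb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  La <- length(ac); Lb <- length(rb)
  best <- 0L; best3 <- 0L
  for (o in (-(Lb - 1L)):(La - 1L)) {
    i <- max(1L, o + 1L):min(La, o + Lb)
    score <- sum(.codes_can_pair[cbind(ac[i], rb[i - o])])
    best <- max(best, score)
    if (La - o >= 1L && La - o <= Lb) best3 <- max(best3, score)
  }
  c(max_anneal = best, max_3prime_anneal = best3)
}

# stem of stem_min possible base pairs closing a loop of >= loop_min
.has_hairpin <- function(chars, stem_min = 4L, loop_min = 3L) {
  L <- length(chars)
  if (L < 2L * stem_min + loop_min) return(FALSE)
  for (i in 1L:(L - 2L * stem_min - loop_min + 1L)) {
    for (j in (i + stem_min + loop_min):(L - stem_min + 1L)) {
      t <- 0L:(stem_min - 1L)
      if (all(.codes_can_pair[cbind(chars[i + t],
                                    chars[j + stem_min - 1L - t])])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' QC thresholds for primer recommendations
#'
#' Defaults: pair Tm difference at most 5 degrees C, 3'-anchored
#' annealing score at most 4 paired bases, GC content between 30 and
#' 70 percent, hairpins flagged from a 4 bp stem.
#'
#' @param tm_diff_max max tolerated Tm difference within a pair (deg C).
#' @param anneal3_max max tolerated 3'-anchored annealing score (bp).
#' @param gc_min,gc_max tolerated GC-content range (percent).
#' @param hairpin_stem_min shortest self-complementary stem (bp, loop of
#'   at least 3 nt) that raises the hairpin flag; `Inf` disables it.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(tm_diff_max = 5, anneal3_max = 4,
                          gc_min = 30, gc_max = 70,
                          hairpin_stem_min = 4) {
  structure(
    list(tm_diff_max = tm_diff_max, anneal3_max = anneal3_max,
         gc_min = gc_min, gc_max = gc_max,
         hairpin_stem_min = hairpin_stem_min),
    class = "qc_thresholds"
  )
}

#' QC report for a single (degenerate) oligo
#'
#' Collects GC content, Wallace and nearest-neighbor Tm, self- and
#' 3'-annealing scores, and a hairpin flag into one report with a
#' recommendation: `ok` with no threshold violations, `caution` with
#' one, `reject` with two or more.
#'
#' @param seq degenerate DNA string.
#' @param thresholds a [qc_thresholds()].
#' @param ... passed to [tm_nn()].
#' @return A list of class `oligo_report`.
#' @export
oligo_qc <- function(seq, thresholds = qc_thresholds(), ...) {
  seq <- as_degenerate(seq)
  gc <- gc_content(seq)
  nn <- tm_nn(seq, ...)
  ann <- annealing_scores(seq)
  hairpin <- is.finite(thresholds$hairpin_stem_min) &&
    .has_hairpin(strsplit(seq, "", fixed = TRUE)[[1]],
                 stem_min = thresholds$hairpin_stem_min)
  violations <- sum(
    gc < thresholds$gc_min || gc > thresholds$gc_max,
    ann[["max_3prime_anneal"]] > thresholds$anneal3_max,
    hairpin
  )
  structure(
    list(
      sequence = seq,
      gc_percent = gc,
      tm_wallace = tm_wallace(seq),
      tm_nn_min = nn[["min"]], tm_nn_mean = nn[["mean"]],
      tm_nn_max = nn[["max"]],
      max_self_anneal = ann[["max_anneal"]],
      max_3prime_anneal = ann[["max_3prime_anneal"]],
      hairpin_flag = hairpin,
      violations = violations,
      recommendation = c("ok", "caution", "reject")[min(violations + 1L, 3L)]
    ),
    class = "oligo_report"
  )
}

#' @export
print.oligo_report <- function(x, ...) {
  cat("<oligo_report ", x$sequence, ">\n", sep = "")
  cat(sprintf("  GC %.1f%%  Tm(Wallace) %.1f C  Tm(NN) %.1f-%.1f C (mean %.1f)\n",
              x$gc_percent, x$tm_wallace, x$tm_nn_min, x$tm_nn_max,
              x$tm_nn_mean))
  cat("  self-anneal", x$max_self_anneal, " 3'-anneal", x$max_3prime_anneal,
      " hairpin", x$hairpin_flag, " ->", x$recommendation, "\n")
  invisible(x)
}

#' QC of a forward/reverse primer pair
#'
#' Runs [oligo_qc()] on both primers and adds the pairwise Tm difference
#' (absolute difference of mean nearest-neighbor Tm). A Tm difference
#' above the threshold downgrades both primers' recommendations by one
#' step (`ok` to `caution`, `caution` to `reject`).
#'
#' @param fwd,rev degenerate primer strings.
#' @param thresholds a [qc_thresholds()].
#' @param ... passed to [tm_nn()].
#' @return A list of class `pair_qc` with components `fwd`, `rev`
#'   (oligo reports), `tm_difference`, `recommendation` (named character
#'   of length 2).
#' @export
qc_pair <- function(fwd, rev, thresholds = qc_thresholds(), ...) {
  qf <- oligo_qc(fwd, thresholds, ...)
  qr <- oligo_qc(rev, thresholds, ...)
  dtm <- abs(qf$tm_nn_mean - qr$tm_nn_mean)
  levels <- c("ok", "caution", "reject")
  rec <- c(fwd = qf$recommendation, rev = qr$recommendation)
  if (dtm > thresholds$tm_diff_max) {
    rec[] <- levels[pmin(match(rec, levels) + 1L, 3L)]
  }
  structure(
    list(fwd = qf, rev = qr, tm_difference = dtm, recommendation = rec),
    class = "pair_qc"
  )
}

#' @export
print.pair_qc <- function(x, ...) {
  cat("<pair_qc>\n  fwd ", x$fwd$sequence, " -> ", x$recommendation[["fwd"]],
      "\n  rev ", x$rev$sequence, " -> ", x$recommendation[["rev"]],
      "\n", sep = "")
  cat(sprintf("  Tm difference %.2f C\n", x$tm_difference))
  invisible(x)
}
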