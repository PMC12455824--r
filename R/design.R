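# Degenerate primer design under a degeneracy cap: a two-phase greedy
# heuristic in the style of classic degenerate-primer-design tools.
# Phase one ("expansion") grows a concrete seed window one code
# enlargement at a time, always taking the enlargement with the best
# coverage gain. Phase two ("contraction") starts from the position-wise
# union of the best-matching window of every record and removes the
# nucleotide whose loss costs fewest covered records until the cap
# holds. Both phases score coverage with the same mismatch rule as
# final reporting, and all tie-breaks are total orders, so design is
# deterministic.

.set_to_code <- local({
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ""), character(1))
  stats::setNames(names(sets), keys)
})

.sets_to_string <- function(sets) {
  paste(vapply(
    sets,
    function(s) .set_to_code[[paste(sort(s), collapse = "")]],
    character(1)
  ), collapse = "")
}

#' Configuration for degenerate primer design
#'
#' @param primer_length designed primer length, bp (>= 8; 16-25 is the
#'   usual working range).
#' @param max_degeneracy degeneracy cap for designed primers.
#' @param rule [mismatch_rule()] used both during design and for
#'   reported coverage.
#' @param fwd_region,rev_region fractional intervals of each gene from
#'   which forward / reverse candidates are drawn (defaults: the two
#'   gene halves, mirroring a typical panel's geometry).
#' @param candidates_kept candidate primers retained per region.
#' @param max_seeds cap on seed windows per region; above it seeds are
#'   subsampled by a deterministic stride (no RNG involved).
#' @param product_size_window admissible `(min, max)` product length, bp.
#' @param seed reserved for samplers; the shipped heuristics are
#'   deterministic and do not consume it.
#' @return A list of class `design_config`.
#' @export
design_config <- function(primer_length = 20L, max_degeneracy = 512,
                          rule = mismatch_rule(),
                          fwd_region = c(0, 0.5), rev_region = c(0.5, 1),
                          candidates_kept = 50L, max_seeds = 40L,
                          product_size_window = c(50, 3000), seed = 1L) {
  stopifnot(
    primer_length >= 8, max_degeneracy >= 1,
    inherits(rule, "mismatch_rule"),
    length(fwd_region) == 2L, length(rev_region) == 2L,
    fwd_region[1] >= 0, fwd_region[2] <= 1, fwd_region[1] < fwd_region[2],
    rev_region[1] >= 0, rev_region[2] <= 1, rev_region[1] < rev_region[2],
    candidates_kept >= 1, max_seeds >= 1,
    product_size_window[1] < product_size_window[2]
  )
  structure(
    list(
      primer_length = as.integer(primer_length),
      max_degeneracy = max_degeneracy,
      rule = rule,
      fwd_region = fwd_region, rev_region = rev_region,
      candidates_kept = as.integer(candidates_kept),
      max_seeds = as.integer(max_seeds),
      product_size_window = product_size_window,
      seed = as.integer(seed)
    ),
    class = "design_config"
  )
}

#' Enumerate concrete seed windows from a library region
#'
#' All length-`L` windows falling inside the configured fractional
#' region of each record, deduplicated in order of first appearance.
#' Windows containing `N` are not usable as seeds and are skipped, as
#' are records shorter than the primer length (with a warning). When
#' more than `max_seeds` distinct windows exist, a deterministic stride
#' subsample is returned.
#'
#' @param lib a [seq_library()].
#' @param config a [design_config()].
#' @param region `"forward"` or `"reverse"` (which fractional interval
#'   to draw from; seeds are always plus-strand windows).
#' @return Character vector of concrete windows.
#' @export
enumerate_seeds <- function(lib, config = design_config(),
                            region = c("forward", "reverse")) {
  region <- match.arg(region)
  stopifnot(inherits(lib, "seq_library"), inherits(config, "design_config"))
  L <- config$primer_length
  frac <- if (region == "forward") config$fwd_region else config$rev_region
  seeds <- character(0)
  for (i in seq_len(nrow(lib))) {
    len <- nchar(lib$sequence[i])
    if (len < L) {
      warning("record '", lib$id[i], "' (", len,
              " bp) is shorter than the primer length; skipped",
              call. = FALSE)
      next
    }
    i1 <- max(1L, floor(frac[1] * len) + 1L)
    i2 <- min(len, ceiling(frac[2] * len))
    if (i2 - i1 + 1L < L) next
    starts <- i1:(i2 - L + 1L)
    w <- substring(lib$sequence[i], starts, starts + L - 1L)
    seeds <- c(seeds, w[!grepl("N", w, fixed = TRUE)])
  }
  seeds <- unique(seeds)
  if (length(seeds) > config$max_seeds) {
    seeds <- seeds[unique(round(seq(1L, length(seeds),
                                    length.out = config$max_seeds)))]
  }
  seeds
}

.design_cov <- function(primer, lib, config, orientation) {
  coverage(primer, lib, config$rule,
           orientation = orientation, primer_id = primer)
}

# --- incremental matching engine for the design loops -------------------
#
# The greedy phases evaluate thousands of single-code edits, and each
# edit touches exactly one primer position, i.e. one column of the
# per-window mismatch matrix. The engine caches, per record, the
# template slice under every scan column plus current per-window 5'/3'
# mismatch sums, so trying an edit costs one column recomputation per
# record -- and only records whose covered status can change are
# rechecked (enlargements can only gain records, removals only lose
# them). Results agree exactly with coverage()/match_sites(); the final
# reported coverage of every designed primer is recomputed through the
# public path.
#
# Scan space vs primer space: forward primers are scanned as written,
# so scan column j is primer position j. Reverse primers are scanned as
# their reverse complement, so scan column j is primer position L+1-j
# and carries the complement sets; the primer's 5' region maps to the
# rightmost columns.

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")

.mk_engine <- function(lib, rule, L, orientation) {
  split <- .resolve_split(rule, L)
  five <- if (orientation == "forward") {
    seq_len(L) <= split
  } else {
    seq_len(L) > L - split
  }
  recs <- lapply(lib$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    nw <- length(chars) - L + 1L
    if (nw < 1L) return(NULL)
    list(tmcols = lapply(seq_len(L), function(j) chars[j:(j + nw - 1L)]))
  })
  e <- new.env(parent = emptyenv())
  e$recs <- recs
  e$five <- five
  e$caps <- c(rule$max_5prime, rule$max_3prime, rule$max_total)
  e$orientation <- orientation
  e$L <- L
  e
}

# primer-space sets -> scan-space sets
.to_scan <- function(sets, orientation) {
  if (orientation == "forward") return(sets)
  lapply(rev(sets), function(s) unname(.comp_base[s]))
}

.eng_covered <- function(e, m5, m3) {
  any(m5 <= e$caps[1] & m3 <= e$caps[2] & (m5 + m3) <= e$caps[3])
}

# (re)initialise the engine state for scan-space sets
.eng_init <- function(e, scan_sets) {
  e$cols <- vector("list", length(e$recs))
  e$m5 <- vector("list", length(e$recs))
  e$m3 <- vector("list", length(e$recs))
  e$covered <- logical(length(e$recs))
  for (r in seq_along(e$recs)) {
    rec <- e$recs[[r]]
    if (is.null(rec)) next
    cols <- lapply(seq_len(e$L), function(j) {
      !(rec$tmcols[[j]] %in% scan_sets[[j]])
    })
    m5 <- Reduce(`+`, lapply(which(e$five), function(j) cols[[j]]))
    m3 <- Reduce(`+`, lapply(which(!e$five), function(j) cols[[j]]))
    e$cols[[r]] <- cols
    e$m5[[r]] <- m5
    e$m3[[r]] <- m3
    e$covered[r] <- .eng_covered(e, m5, m3)
  }
  invisible(e)
}

# matched count if scan column j had base set new_set; direction
# "enlarge" can only add covered records, "shrink" only drop them
.eng_try <- function(e, j, new_set, direction) {
  check <- if (direction == "enlarge") which(!e$covered) else which(e$covered)
  matched <- sum(e$covered)
  for (r in check) {
    if (is.null(e$recs[[r]])) next
    new_col <- !(e$recs[[r]]$tmcols[[j]] %in% new_set)
    d <- new_col - e$cols[[r]][[j]]
    if (e$five[j]) {
      cov <- .eng_covered(e, e$m5[[r]] + d, e$m3[[r]])
    } else {
      cov <- .eng_covered(e, e$m5[[r]], e$m3[[r]] + d)
    }
    if (direction == "enlarge" && cov) matched <- matched + 1L
    if (direction == "shrink" && !cov) matched <- matched - 1L
  }
  matched
}

# commit scan column j <- new_set
.eng_apply <- function(e, j, new_set) {
  for (r in seq_along(e$recs)) {
    if (is.null(e$recs[[r]])) next
    new_col <- !(e$recs[[r]]$tmcols[[j]] %in% new_set)
    d <- new_col - e$cols[[r]][[j]]
    e$cols[[r]][[j]] <- new_col
    if (e$five[j]) e$m5[[r]] <- e$m5[[r]] + d else e$m3[[r]] <- e$m3[[r]] + d
    e$covered[r] <- .eng_covered(e, e$m5[[r]], e$m3[[r]])
  }
  invisible(e)
}

# primer position/base edit -> scan column/base
.to_scan_edit <- function(i, b, L, orientation) {
  if (orientation == "forward") list(j = i, b = b)
  else list(j = L + 1L - i, b = unname(.comp_base[b]))
}

.designed <- function(sets, lib, config, orientation, origin) {
  primer <- .sets_to_string(sets)
  structure(
    list(
      sequence = primer,
      degeneracy = degeneracy(primer),
      coverage = .design_cov(primer, lib, config, orientation),
      origin = origin,
      region = orientation
    ),
    class = "designed_primer"
  )
}

#' @export
print.designed_primer <- function(x, ...) {
  cat(
    "<designed_primer (", x$origin, ", ", x$region, "): ", x$sequence,
    ", degeneracy ", x$degeneracy, ", coverage ", x$coverage$matched, "/",
    x$coverage$total, ">\n",
    sep = ""
  )
  invisible(x)
}

#' Grow a concrete seed into a degenerate primer (expansion phase)
#'
#' Starting from a concrete window (degeneracy 1), repeatedly applies
#' the single (position, added nucleotide) code enlargement that
#' maximises the coverage gain under the design's mismatch rule,
#' stopping when no enlargement gains coverage or every enlargement
#' would exceed the degeneracy cap. Ties are broken by smaller
#' resulting degeneracy, then leftmost position, then alphabetical
#' nucleotide. The seed is in primer orientation: pass the reverse
#' complement of a plus-strand window when designing a reverse primer.
#'
#' @param seed concrete DNA string of length `config$primer_length`.
#' @param lib a [seq_library()].
#' @param config a [design_config()].
#' @param orientation `"forward"` or `"reverse"` (how coverage is
#'   evaluated; see [coverage()]).
#' @return A `designed_primer` (fields: `sequence`, `degeneracy`,
#'   `coverage`, `origin`, `region`).
#' @export
expand_seed <- function(seed, lib, config = design_config(),
                        orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seed <- as_degenerate(seed, "seed")
  stopifnot(nchar(seed) == config$primer_length, degeneracy(seed) == 1)
  sets <- .seq_sets(seed)
  L <- length(sets)
  eng <- .mk_engine(lib, config$rule, L, orientation)
  .eng_init(eng, .to_scan(sets, orientation))
  deg <- 1
  cov_cur <- sum(eng$covered)
  repeat {
    if (cov_cur == nrow(lib)) break   # nothing left to gain
    best <- NULL
    for (i in seq_len(L)) {
      new_deg <- deg / length(sets[[i]]) * (length(sets[[i]]) + 1L)
      if (new_deg > config$max_degeneracy) next
      for (b in setdiff(c("A", "C", "G", "T"), sets[[i]])) {
        ed <- .to_scan_edit(i, b, L, orientation)
        scan_set <- .to_scan(sets, orientation)[[ed$j]]
        cov <- .eng_try(eng, ed$j, c(scan_set, ed$b), "enlarge")
        gain <- cov - cov_cur
        better <- is.null(best) ||
          gain > best$gain ||
          (gain == best$gain && new_deg < best$deg) ||
          (gain == best$gain && new_deg == best$deg && i < best$i) ||
          (gain == best$gain && new_deg == best$deg && i == best$i &&
             b < best$b)
        if (better) best <- list(gain = gain, deg = new_deg, i = i, b = b)
      }
    }
    if (is.null(best) || best$gain <= 0) break
    sets[[best$i]] <- c(sets[[best$i]], best$b)
    deg <- best$deg
    ed <- .to_scan_edit(best$i, best$b, L, orientation)
    .eng_apply(eng, ed$j, .to_scan(sets, orientation)[[ed$j]])
    cov_cur <- sum(eng$covered)
  }
  .designed(sets, lib, config, orientation, origin = "expansion")
}

# best-matching window of a record against a concrete target (site
# space): minimal mismatch count, ties to the smallest start. N in the
# record always counts as a mismatch here (a seed alignment, not a
# primer match).
.best_window <- function(target_chars, sequence) {
  L <- length(target_chars)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  nw <- length(chars) - L + 1L
  if (nw < 1L) return(NULL)
  mm <- integer(nw)
  for (i in seq_len(L)) {
    mm <- mm + (chars[i:(i + nw - 1L)] != target_chars[i])
  }
  w <- which.min(mm)
  chars[w:(w + L - 1L)]
}

#' Contract the library-wide union of a seed's windows (contraction phase)
#'
#' Aligns the seed to each record's best-matching window (minimal
#' mismatches, leftmost tie-break), takes the position-wise union of
#' the aligned bases (in primer orientation) and then greedily removes
#' the single nucleotide whose removal loses the fewest covered records
#' -- ties to the rightmost position, then alphabetical nucleotide --
#' until the degeneracy cap holds.
#'
#' @inheritParams expand_seed
#' @return A `designed_primer` with `origin = "contraction"`.
#' @export
contract_union <- function(seed, lib, config = design_config(),
                           orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seed <- as_degenerate(seed, "seed")
  stopifnot(nchar(seed) == config$primer_length, degeneracy(seed) == 1)
  # the plus-strand pattern whose windows we align to
  target <- if (orientation == "forward") seed else revcomp(seed)
  target_chars <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(target_chars)
  seed_chars <- strsplit(seed, "", fixed = TRUE)[[1]]
  sets <- lapply(seed_chars, function(b) b)
  for (i in seq_len(nrow(lib))) {
    w <- .best_window(target_chars, lib$sequence[i])
    if (is.null(w)) next
    if (orientation == "reverse") {
      w <- strsplit(revcomp(paste(w, collapse = "")), "", fixed = TRUE)[[1]]
    }
    for (p in seq_len(L)) {
      if (w[p] != "N") sets[[p]] <- union(sets[[p]], w[p])
    }
  }
  deg <- prod(lengths(sets))
  eng <- .mk_engine(lib, config$rule, L, orientation)
  .eng_init(eng, .to_scan(sets, orientation))
  cov_cur <- sum(eng$covered)
  while (deg > config$max_degeneracy) {
    best <- NULL
    for (i in seq_along(sets)) {
      if (length(sets[[i]]) < 2L) next
      for (b in sets[[i]]) {
        ed <- .to_scan_edit(i, b, L, orientation)
        new_scan <- setdiff(.to_scan(sets, orientation)[[ed$j]], ed$b)
        cov <- .eng_try(eng, ed$j, new_scan, "shrink")
        lost <- cov_cur - cov
        better <- is.null(best) ||
          lost < best$lost ||
          (lost == best$lost && i > best$i) ||
          (lost == best$lost && i == best$i && b < best$b)
        if (better) best <- list(lost = lost, i = i, b = b, cov = cov)
      }
    }
    sets[[best$i]] <- setdiff(sets[[best$i]], best$b)
    deg <- prod(lengths(sets))
    ed <- .to_scan_edit(best$i, best$b, L, orientation)
    .eng_apply(eng, ed$j, .to_scan(sets, orientation)[[ed$j]])
    cov_cur <- best$cov
  }
  .designed(sets, lib, config, orientation, origin = "contraction")
}

# run both heuristics over every seed of a region; returns a ranked,
# deduplicated list of designed primers
.region_candidates <- function(lib, config, orientation) {
  region <- orientation
  seeds <- enumerate_seeds(lib, config, region = region)
  if (orientation == "reverse") seeds <- vapply(seeds, revcomp, character(1))
  cands <- list()
  seen <- character(0)
  for (s in seeds) {
    for (fn in list(expand_seed, contract_union)) {
      d <- fn(s, lib, config, orientation)
      if (!d$sequence %in% seen) {
        seen <- c(seen, d$sequence)
        cands[[length(cands) + 1L]] <- d
      }
    }
  }
  if (!length(cands)) return(cands)
  ord <- order(
    -vapply(cands, function(d) d$coverage$matched, numeric(1)),
    vapply(cands, function(d) d$degeneracy, numeric(1)),
    vapply(cands, function(d) d$sequence, character(1))
  )
  cands[ord][seq_len(min(length(cands), config$candidates_kept))]
}

#' Design ranked forward/reverse degenerate primer pairs
#'
#' Generates candidate primers in the forward and reverse regions with
#' both heuristics ([expand_seed()], [contract_union()]), then pairs
#' them. A pair is admissible when on at least one record an
#' orientation-consistent site pair yields a product length inside the
#' configured window. Pairs are ranked by joint coverage
#' ([pair_coverage()]), then by summed degeneracy (ascending), then by
#' sequence.
#'
#' @param lib a [seq_library()].
#' @param config a [design_config()].
#' @return A `data.frame` of class `design_result`, one row per
#'   admissible pair: primer sequences, degeneracies, single-primer and
#'   pair coverage, and the expected amplicon size (median per-record
#'   product length). Attribute `product_sizes` holds the per-record
#'   product lengths of each pair. Zero rows (with a `diagnostic`
#'   attribute) when no pair is admissible.
#' @export
design_pairs <- function(lib, config = design_config()) {
  stopifnot(inherits(lib, "seq_library"), inherits(config, "design_config"))
  fwd_c <- .region_candidates(lib, config, "forward")
  rev_c <- .region_candidates(lib, config, "reverse")
  empty <- data.frame(
    fwd = character(), rev = character(),
    fwd_degeneracy = numeric(), rev_degeneracy = numeric(),
    fwd_matched = integer(), rev_matched = integer(),
    pair_matched = integer(), total = integer(),
    expected_bp = numeric(), stringsAsFactors = FALSE
  )
  class(empty) <- c("design_result", "data.frame")
  if (!length(fwd_c) || !length(rev_c)) {
    attr(empty, "diagnostic") <- "no candidate primers in one or both regions"
    return(empty)
  }
  # cache per-record sites of every candidate so pairing never rescans
  site_cache <- function(cands, strand) {
    lapply(cands, function(d) {
      lapply(seq_len(nrow(lib)), function(i) {
        match_sites(d$sequence, lib$sequence[i], config$rule,
                    strand = strand, template_id = lib$id[i])
      })
    })
  }
  fwd_sites <- site_cache(fwd_c, "plus")
  rev_sites <- site_cache(rev_c, "minus")
  rows <- list()
  sizes <- list()
  win <- config$product_size_window
  for (a in seq_along(fwd_c)) {
    for (b in seq_along(rev_c)) {
      per_record <- rep(NA_integer_, nrow(lib))
      for (i in seq_len(nrow(lib))) {
        fs <- fwd_sites[[a]][[i]]; rs <- rev_sites[[b]][[i]]
        if (!nrow(fs) || !nrow(rs)) next
        combos <- expand.grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
        len <- rs$end[combos$r] - fs$start[combos$f]
        ok <- rs$start[combos$r] >= fs$end[combos$f] &
          len >= win[1] & len <= win[2]
        if (!any(ok)) next
        mm <- fs$mismatch_total[combos$f] + rs$mismatch_total[combos$r]
        pick <- which(ok)[order(mm[ok], len[ok])][1L]
        per_record[i] <- len[pick]
      }
      if (all(is.na(per_record))) next   # inadmissible pair
      pair_matched <- sum(!is.na(per_record))
      rows[[length(rows) + 1L]] <- data.frame(
        fwd = fwd_c[[a]]$sequence, rev = rev_c[[b]]$sequence,
        fwd_degeneracy = fwd_c[[a]]$degeneracy,
        rev_degeneracy = rev_c[[b]]$degeneracy,
        fwd_matched = fwd_c[[a]]$coverage$matched,
        rev_matched = rev_c[[b]]$coverage$matched,
        pair_matched = pair_matched,
        total = nrow(lib),
        expected_bp = stats::median(per_record, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
      sizes[[length(sizes) + 1L]] <- per_record
    }
  }
  if (!length(rows)) {
    attr(empty, "diagnostic") <-
      "no orientation-consistent pair with an in-window product"
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$pair_matched, out$fwd_degeneracy + out$rev_degeneracy,
               out$fwd, out$rev)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "product_sizes") <- sizes[ord]
  class(out) <- c("design_result", "data.frame")
  out
}

#' @export
print.design_result <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<design_result: no admissible pairs (",
        attr(x, "diagnostic"), ")>\n", sep = "")
    return(invisible(x))
  }
  cat("<design_result: ", nrow(x), " pair(s)>\n", sep = "")
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
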