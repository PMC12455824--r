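# Panel screening: run a primer panel over organisms' sequences and emit
# a class-presence matrix with supporting amplicons and non-specific
# products flagged.

#' Screen organisms with a phaC primer panel
#'
#' For each organism (a [seq_library()] of one or more contigs), every
#' panel pair is simulated on every contig. A class is called present
#' ("+") only when at least one specific amplicon (expected size within
#' tolerance) supports it:
#'
#' * classes I, II and III are called by their dedicated pairs;
#' * class IV is inferred: "+" when the combined III/IV pair is specific
#'   while the class III pair is negative. A positive III/IV pair next
#'   to a positive class III pair reinforces the III call and does not
#'   create a IV call. Inferred IV calls are flagged in the result.
#'
#' All non-specific products (wrong-size bands) are retained in
#' `warnings`, never silently dropped.
#'
#' @param organisms a single [seq_library()] or a list of them (one per
#'   organism); organism ids default to library labels.
#' @param panel a `phac_panel` / list of [primer_pair()].
#' @param rule a [mismatch_rule()].
#' @param size_window,size_tolerance,veto_3prime see [simulate_pcr()].
#' @return A list of class `screening_set`; each element is a
#'   `screening_result` with `organism_id`, `calls` (named "+"/"-"
#'   vector over classes I-IV), `evidence` (specific amplicons),
#'   `warnings` (non-specific amplicons) and `inferred_iv`.
#' @export
screen_panel <- function(organisms, panel = phac_panel(),
                         rule = mismatch_rule(), size_window = c(50, 3000),
                         size_tolerance = 0.2, veto_3prime = TRUE) {
  if (inherits(organisms, "seq_library")) organisms <- list(organisms)
  stopifnot(length(organisms) >= 1L, length(panel) >= 1L)
  for (p in panel) stopifnot(inherits(p, "primer_pair"))
  results <- lapply(organisms, function(lib) {
    stopifnot(inherits(lib, "seq_library"))
    amps <- do.call(rbind, lapply(panel, function(pair) {
      do.call(rbind, lapply(seq_len(nrow(lib)), function(i) {
        simulate_pcr(pair, lib$sequence[i], rule, size_window,
                     size_tolerance, veto_3prime, template_id = lib$id[i])
      }))
    }))
    if (is.null(amps)) amps <- .empty_amplicons()
    specific <- amps[amps$size_ok, , drop = FALSE]
    nonspecific <- amps[!amps$size_ok, , drop = FALSE]
    pair_pos <- function(cls) {
      any(specific$class_label == cls)
    }
    calls <- c(
      I = if (pair_pos("I")) "+" else "-",
      II = if (pair_pos("II")) "+" else "-",
      III = if (pair_pos("III")) "+" else "-",
      IV = "-"
    )
    inferred_iv <- pair_pos("III/IV") && !pair_pos("III")
    if (pair_pos("IV")) inferred_iv <- FALSE  # dedicated IV pair, if any
    if (pair_pos("IV") || inferred_iv) calls[["IV"]] <- "+"
    # integrity: every "+" is backed by at least one specific amplicon
    backing <- c(
      I = "I", II = "II", III = "III",
      IV = if (pair_pos("IV")) "IV" else "III/IV"
    )
    for (cls in names(calls)) {
      if (calls[[cls]] == "+") {
        stopifnot(any(specific$class_label == backing[[cls]]))
      }
    }
    structure(
      list(
        organism_id = attr(lib, "label"),
        calls = calls,
        evidence = specific,
        warnings = nonspecific,
        inferred_iv = inferred_iv
      ),
      class = "screening_result"
    )
  })
  structure(results, class = "screening_set")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result ", x$organism_id, ": ",
      paste(names(x$calls), x$calls, sep = "", collapse = " "),
      if (x$inferred_iv) " (IV inferred from III/IV pair)", ">\n", sep = "")
  invisible(x)
}

#' Screening results as a class matrix
#'
#' @param results a `screening_set` from [screen_panel()].
#' @return `data.frame` with one row per organism: calls for classes
#'   I-IV, counts of specific and non-specific products, and whether the
#'   IV call was inferred from the III/IV pair.
#' @export
screen_matrix <- function(results) {
  stopifnot(inherits(results, "screening_set"), length(results) >= 1L)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      organism_id = r$organism_id,
      I = r$calls[["I"]], II = r$calls[["II"]],
      III = r$calls[["III"]], IV = r$calls[["IV"]],
      n_specific = nrow(r$evidence),
      n_nonspecific = nrow(r$warnings),
      inferred_iv = r$inferred_iv,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' @export
print.screening_set <- function(x, ...) {
  cat("<screening_set: ", length(x), " organism(s)>\n", sep = "")
  print(screen_matrix(x), row.names = FALSE)
  invisible(x)
}

#' Write a screening report
#'
#' TSV and JSON renderings carry identical calls; [read_screen_report()]
#' round-trips either.
#'
#' @param results a `screening_set`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  mat <- screen_matrix(results)   # errors on empty results
  if (format == "tsv") {
    utils::write.table(mat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(mat, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read back a screening report
#'
#' @param path report path written by [write_screen_report()].
#' @param format `"tsv"` or `"json"`.
#' @return The call matrix `data.frame`.
#' @export
read_screen_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(I = "character", II = "character",
                                     III = "character", IV = "character"))
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
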