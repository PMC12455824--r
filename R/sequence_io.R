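# Sequence libraries: ordered collections of concrete DNA records with
# optional class labels, read from / written to multi-record FASTA.

#' Construct a sequence library
#'
#' A sequence library is an ordered collection of concrete DNA records
#' (A/C/G/T plus N for ambiguous template positions), each with a unique
#' non-empty id and an optional phaC class label. Internally a
#' `data.frame` with columns `id`, `sequence`, `class_label` and a
#' `label` attribute naming the library.
#'
#' @param id character vector of unique, non-empty record ids.
#' @param sequence character vector of DNA sequences (case-insensitive;
#'   normalised to upper case).
#' @param class_label optional character vector of class labels
#'   (e.g. "I".."IV"); `NA` where unknown.
#' @param label library name.
#' @return An object of class `seq_library`.
#' @examples
#' lib <- seq_library(c("a", "b"), c("ACGTACGT", "TTGGCCAA"))
#' @export
seq_library <- function(id, sequence, class_label = NA_character_,
                        label = "library") {
  if (length(id) < 1L) stop("a sequence library needs >= 1 record", call. = FALSE)
  id <- as.character(id)
  if (anyNA(id) || any(!nzchar(id))) {
    stop("record ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop(
      "duplicate record id(s): ",
      paste(unique(id[duplicated(id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(sequence) != length(id)) {
    stop("id and sequence must have the same length", call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  for (i in seq_along(sequence)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    if (length(chars) < 1L) {
      stop("record '", id[i], "' has an empty sequence", call. = FALSE)
    }
    bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
    if (length(bad)) {
      stop(
        "record '", id[i], "': non-nucleotide character '",
        chars[bad[1]], "' at position ", bad[1],
        call. = FALSE
      )
    }
  }
  class_label <- rep_len(as.character(class_label), length(id))
  out <- data.frame(
    id = id, sequence = sequence, class_label = class_label,
    stringsAsFactors = FALSE
  )
  attr(out, "label") <- label
  class(out) <- c("seq_library", "data.frame")
  out
}

#' @export
print.seq_library <- function(x, ...) {
  cat(
    "<seq_library '", attr(x, "label"), "': ", nrow(x), " record(s), ",
    "lengths ", min(nchar(x$sequence)), "-", max(nchar(x$sequence)),
    " bp>\n",
    sep = ""
  )
  n_show <- min(nrow(x), 6L)
  for (i in seq_len(n_show)) {
    cl <- if (is.na(x$class_label[i])) "" else paste0(" [class ", x$class_label[i], "]")
    cat("  ", x$id[i], cl, ": ", nchar(x$sequence[i]), " bp\n", sep = "")
  }
  if (nrow(x) > n_show) cat("  ... and", nrow(x) - n_show, "more\n")
  invisible(x)
}

#' Read a sequence library from a FASTA file
#'
#' One record per FASTA entry, in file order. The record id is the first
#' whitespace-delimited token of the header; a `class=<label>` key
#' anywhere in the description is parsed into `class_label`. Sequences
#' are upper-cased; only A/C/G/T/N are accepted (real contigs contain N,
#' so it is allowed here -- its matching semantics are a matching-time
#' policy, see [match_sites()]).
#'
#' @param path FASTA file path.
#' @param label library name; defaults to the file name.
#' @return A [seq_library()].
#' @export
read_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  cls <- rep(NA_character_, length(headers))
  has_cls <- grepl("\\bclass=\\S+", headers)
  cls[has_cls] <- sub("^.*\\bclass=(\\S+).*$", "\\1", headers[has_cls])
  seq_library(ids, as.character(set), cls, label = label)
}

#' Write a sequence library to FASTA
#'
#' Sequence lines are wrapped at 60 columns. Class labels are emitted as
#' a `class=` key in the description so that
#' `read_fasta(write_fasta(lib, f))` reproduces ids, sequences and class
#' labels exactly.
#'
#' @param lib a [seq_library()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "seq_library"))
  if (nrow(lib) < 1L) stop("refusing to write an empty library", call. = FALSE)
  headers <- ifelse(
    is.na(lib$class_label),
    lib$id,
    paste0(lib$id, " class=", lib$class_label)
  )
  set <- Biostrings::DNAStringSet(lib$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
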