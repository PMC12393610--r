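#' Circular DNA sequences
#'
#' A `circular_sequence` is a nucleotide string over `A`/`C`/`G`/`T` together
#' with a circularity flag and a label naming the 1-based numbering
#' convention (the declared origin). Position arithmetic is modulo the
#' length when the sequence is circular: position `L` is followed by
#' position 1. Positions are 1-based and intervals are inclusive throughout
#' the package, matching the convention used for minicircle coordinates in
#' the structural literature.
#'
#' @param residues Single string over `A`/`C`/`G`/`T` (case-insensitive).
#' @param circular Logical; is the molecule covalently closed?
#' @param origin_label Free text naming the numbering convention, e.g. the
#'   reference that assigned position 1.
#'
#' @return An object of class `circular_sequence`.
#' @examples
#' cs <- circular_sequence("GAATTC", circular = TRUE)
#' seq_length(cs)
#' @export
circular_sequence <- function(residues, circular = TRUE,
                              origin_label = "position 1 as written") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    abort("`residues` must be a single non-NA string.")
  }
  residues <- toupper(residues)
  bad <- stringr::str_locate(residues, "[^ACGT]")[1, "start"]
  if (!is.na(bad)) {
    abort(sprintf(
      "non-canonical symbol '%s' at position %d (only A/C/G/T allowed)",
      substr(residues, bad, bad), bad
    ))
  }
  if (nchar(residues) < 1L) abort("sequence must have length >= 1")
  structure(
    list(residues = residues, circular = isTRUE(circular),
         origin_label = origin_label),
    class = "circular_sequence"
  )
}

#' @export
print.circular_sequence <- function(x, ...) {
  L <- nchar(x$residues)
  cat(sprintf("<circular_sequence> %d bp, %s\n", L,
              if (x$circular) "circular" else "linear"))
  cat("  origin: ", x$origin_label, "\n", sep = "")
  shown <- if (L > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("  ", shown, "\n", sep = "")
  invisible(x)
}

#' @rdname circular_sequence
#' @param x Object to coerce (string or `circular_sequence`).
#' @export
as_circular_sequence <- function(x, circular = TRUE,
                                 origin_label = "position 1 as written") {
  if (inherits(x, "circular_sequence")) return(x)
  circular_sequence(x, circular = circular, origin_label = origin_label)
}

#' @rdname circular_sequence
#' @export
seq_length <- function(x) nchar(as_circular_sequence(x)$residues)

#' Read a (possibly circular) DNA sequence from FASTA
#'
#' The first record of the file is used. Circularity can be declared either
#' with the `circular` argument or with the keyword `circular=true` anywhere
#' in the FASTA header.
#'
#' @param path FASTA file.
#' @param circular `NA` (default) to honour a `circular=true` header keyword,
#'   otherwise a logical override.
#' @return A [circular_sequence()].
#' @export
read_circular_fasta <- function(path, circular = NA) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) abort(sprintf("no sequences in '%s'", path))
  header <- names(set)[1]
  circ <- if (is.na(circular)) {
    stringr::str_detect(tolower(header %||% ""), "circular=true")
  } else {
    isTRUE(circular)
  }
  circular_sequence(as.character(set[[1]]), circular = circ,
                    origin_label = header %||% basename(path))
}

#' Write a circular sequence to FASTA
#'
#' The header records the origin label and, for circular molecules, the
#' `circular=true` keyword that [read_circular_fasta()] recognises.
#'
#' @param x A [circular_sequence()] or nucleotide string.
#' @param path Output file.
#' @param name Record name; defaults to the origin label.
#' @return `path`, invisibly.
#' @export
write_circular_fasta <- function(x, path, name = NULL) {
  x <- as_circular_sequence(x)
  name <- name %||% x$origin_label
  if (x$circular && !stringr::str_detect(tolower(name), "circular=true")) {
    name <- paste(name, "circular=true")
  }
  set <- Biostrings::DNAStringSet(x$residues)
  names(set) <- name
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param s Nucleotide string over A/C/G/T.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## 1-based circular position arithmetic: fold any integer onto 1..L
circ_pos <- function(i, L) ((i - 1L) %% L) + 1L

## inclusive (possibly wrapping) window of `len` positions starting at
## `start`; errors if a linear sequence cannot hold it
circ_window <- function(start, len, L, circular) {
  idx <- start + seq_len(len) - 1L
  if (!circular && (start < 1L || max(idx) > L)) {
    abort(sprintf("window [%d, %d] does not fit a linear sequence of length %d",
                  start, start + len - 1L, L))
  }
  circ_pos(idx, L)
}

## substring of a circular_sequence over a wrapped window
circ_substr <- function(x, start, len) {
  x <- as_circular_sequence(x)
  L <- seq_length(x)
  idx <- circ_window(start, len, L, x$circular)
  paste(strsplit(x$residues, "", fixed = TRUE)[[1]][idx], collapse = "")
}
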