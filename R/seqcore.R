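# Sequence representation, validation, FASTA I/O and elementary sequence
# arithmetic. All coordinates in this package are 1-based, closed intervals
# (the R/Bioconductor convention).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.DNA_CODES <- stats::setNames(seq_along(DNA_ALPHABET), DNA_ALPHABET)
.N_CODE <- .DNA_CODES[["N"]]
# complement code lookup: A<->T, C<->G, N->N
.COMP_CODE <- c(4L, 3L, 2L, 1L, 5L)

#' Validate a DNA string
#'
#' Upper-cases the input and checks it against the package alphabet
#' \{A, C, G, T, N\}. Other IUPAC ambiguity codes are rejected so the
#' exhaustive matcher's semantics stay unambiguous.
#'
#' @param s character scalar.
#' @param what label used in error messages.
#' @param allow_empty permit the empty string (default FALSE).
#' @return the validated, upper-case string.
#' @export
validate_bases <- function(s, what = "sequence", allow_empty = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  s <- toupper(s)
  if (!allow_empty && nchar(s) == 0L) {
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 substr(s, bad, bad), bad, what), call. = FALSE)
  }
  s
}

#' Construct a DNA sequence object
#'
#' A light container pairing an identifier with a validated DNA string.
#'
#' @param bases DNA string over \{A, C, G, T, N\}; case-insensitive.
#' @param id text identifier.
#' @return an object of class \code{dna_seq} with fields \code{id} and
#'   \code{bases}.
#' @export
dna_sequence <- function(bases, id = "seq") {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  structure(list(id = id, bases = validate_bases(bases)), class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$bases)
  shown <- if (n > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat(sprintf("<dna_seq> %s (%d bp)\n%s\n", x$id, n, shown))
  invisible(x)
}

# Accept either a dna_seq or a plain string; return validated bases.
as_bases <- function(x, what = "sequence", allow_empty = FALSE) {
  if (inherits(x, "dna_seq")) x$bases else validate_bases(x, what, allow_empty)
}

seq_id <- function(x, default = "seq") {
  if (inherits(x, "dna_seq")) x$id else default
}

# integer encoding (A=1 C=2 G=3 T=4 N=5) for fast positional comparison
encode_dna <- function(s) {
  unname(.DNA_CODES[strsplit(s, "", fixed = TRUE)[[1L]]])
}

decode_dna <- function(codes) {
  paste(DNA_ALPHABET[codes], collapse = "")
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; N maps to N.
#'
#' @param s DNA string or \code{dna_seq}.
#' @return the reverse-complement string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(s) {
  b <- as_bases(s, allow_empty = TRUE)
  if (nchar(b) == 0L) return(b)
  comp <- chartr("ACGTN", "TGCAN", b)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' GC content
#'
#' Fraction of G and C bases. Ns count in the denominator only, so an
#' N-containing oligo is penalised rather than ignored.
#'
#' @param s DNA string or \code{dna_seq}; non-empty.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(s) {
  b <- as_bases(s)
  codes <- encode_dna(b)
  sum(codes == 2L | codes == 3L) / length(codes)
}

#' Read a FASTA file
#'
#' Parses a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' list of \code{dna_seq} objects. The id is the header text after ">" up to
#' the first whitespace. Lower-case bases are normalised to upper case;
#' blank lines are tolerated. Malformed input (leading non-FASTA content,
#' records with no sequence) raises a parse error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return list of \code{dna_seq}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header, got '%s'",
                 first, lines[first]), call. = FALSE)
  }
  headers <- which(startsWith(trimws(lines), ">"))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    body <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)[
      seq_len(max(0L, bounds[i + 1L] - headers[i] - 1L))]]
    if (sum(nchar(trimws(body))) == 0L) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has an empty sequence",
                   headers[i], sub("^>\\s*", "", trimws(lines[headers[i]]))),
           call. = FALSE)
    }
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) dna_sequence(as.character(set[[i]]), id = ids[i]))
}

#' Write sequences to a FASTA file
#'
#' @param seqs a \code{dna_seq}, a list of them, or a named character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- mapply(dna_sequence, seqs, ids, SIMPLIFY = FALSE)
  }
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
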