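# Exhaustive, non-heuristic detection of primer binding sites and
# enumeration of potential PCR products. Every offset on both strands is
# scanned (no seeding heuristic), so every site satisfying the match
# parameters is guaranteed to be found -- including the evenly-spaced-
# mismatch sites that alignment heuristics can miss. Any alternative
# secondary-binding backend must implement the same find/count surface.

#' Binding-site match parameters
#'
#' @param max_mismatches maximum substitutions over the full primer length;
#'   \code{NULL} (the default) means \code{floor(primer length / 5)}.
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match exactly (default 5); set 0 for a pure Hamming criterion.
#' @param both_strands search the minus strand too (default TRUE).
#' @return an object of class \code{match_params}.
#' @export
match_params <- function(max_mismatches = NULL, three_prime_exact = 5L,
                         both_strands = TRUE) {
  if (!is.null(max_mismatches)) stopifnot(max_mismatches >= 0)
  stopifnot(three_prime_exact >= 0L, is.logical(both_strands))
  structure(list(max_mismatches = max_mismatches,
                 three_prime_exact = as.integer(three_prime_exact),
                 both_strands = isTRUE(both_strands)),
            class = "match_params")
}

.resolve_max_mm <- function(p, primer_len) {
  if (is.null(p$max_mismatches)) primer_len %/% 5L else as.integer(p$max_mismatches)
}

.empty_sites <- function(status = "ok") {
  out <- data.frame(template_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    mismatches = integer(), stringsAsFactors = FALSE)
  attr(out, "status") <- status
  out
}

# Mismatch counts of the pattern at every offset of the template, plus the
# count restricted to the positions listed in exact_pos (primer 3' block).
# Ns on either side never count as a match.
.scan_offsets <- function(pat_codes, tmpl_codes, exact_pos) {
  m <- length(pat_codes)
  n <- length(tmpl_codes)
  k <- n - m + 1L
  mm <- integer(k)
  mm_exact <- integer(k)
  idx <- seq_len(k)
  for (j in seq_len(m)) {
    tj <- tmpl_codes[idx + (j - 1L)]
    neq <- tj != pat_codes[j] | tj == .N_CODE | pat_codes[j] == .N_CODE
    mm <- mm + neq
    if (j %in% exact_pos) mm_exact <- mm_exact + neq
  }
  list(mm = mm, mm_exact = mm_exact)
}

#' Find all binding sites of a primer on a template
#'
#' Exhaustively scans every position of the template (both strands unless
#' disabled) for ungapped matches of the primer with at most
#' \code{max_mismatches} substitutions and an exactly matching 3'-terminal
#' block of \code{three_prime_exact} bases. Minus-strand hits are reported in
#' plus-strand coordinates; there the primer's 3' end lies at the site's low
#' coordinate.
#'
#' @param primer primer DNA string (or \code{dna_seq}).
#' @param template template \code{dna_seq} or DNA string.
#' @param p a \code{match_params} object.
#' @return data.frame with columns \code{template_id}, \code{start},
#'   \code{end} (1-based, closed), \code{strand} (\code{"+"}/\code{"-"}) and
#'   \code{mismatches}, sorted by start then strand. A primer longer than the
#'   template yields an empty frame with attribute \code{status}.
#' @export
find_binding_sites <- function(primer, template, p = match_params()) {
  pb <- as_bases(primer, "primer")
  tb <- as_bases(template, "template")
  tid <- seq_id(template, "template")
  m <- nchar(pb)
  if (m > nchar(tb)) return(.empty_sites("primer longer than template"))
  max_mm <- .resolve_max_mm(p, m)
  tpe <- min(p$three_prime_exact, m)
  tmpl_codes <- encode_dna(tb)

  collect <- function(pat, exact_pos, strand) {
    sc <- .scan_offsets(encode_dna(pat), tmpl_codes, exact_pos)
    hit <- which(sc$mm <= max_mm & sc$mm_exact == 0L)
    if (length(hit) == 0L) return(NULL)
    data.frame(template_id = tid, start = hit, end = hit + m - 1L,
               strand = strand, mismatches = sc$mm[hit],
               stringsAsFactors = FALSE)
  }
  # plus strand: 3' end of the primer = last tpe pattern positions
  plus <- collect(pb, if (tpe > 0L) seq.int(m - tpe + 1L, m) else integer(), "+")
  minus <- NULL
  if (p$both_strands) {
    # minus strand: scan the reverse complement; the primer's 3'-terminal
    # bases map to the first tpe positions of the pattern
    minus <- collect(reverse_complement(pb),
                     if (tpe > 0L) seq_len(tpe) else integer(), "-")
  }
  out <- rbind(plus, minus)
  if (is.null(out)) return(.empty_sites())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}

#' Count binding sites
#'
#' @inheritParams find_binding_sites
#' @return integer site count.
#' @export
count_binding_sites <- function(primer, template, p = match_params()) {
  nrow(find_binding_sites(primer, template, p))
}

#' Enumerate potential PCR products
#'
#' Finds every plus-strand site of the forward primer and every minus-strand
#' site of the reverse primer, then emits one product per convergent pair
#' whose length (reverse end - forward start + 1) is positive and at most
#' \code{max_product_length}. The intended target amplicon appears as one of
#' the products; more than one product signals potential secondary products.
#' The default window of 3500 bases reflects a typical polymerase extension
#' budget (about 1000 bases per minute).
#'
#' @param forward,reverse primer DNA strings (or \code{dna_seq}).
#' @param template template \code{dna_seq} or DNA string.
#' @param max_product_length maximum amplicon length in bases (default 3500).
#' @param p a \code{match_params} object.
#' @param include_same_primer also pair forward x forward and
#'   reverse x reverse convergent sites (default FALSE).
#' @return data.frame with one row per product: forward/reverse site
#'   coordinates, mismatch counts, primer roles and \code{product_length}.
#' @export
search_for_pcr_products <- function(forward, reverse, template,
                                    max_product_length = 3500L,
                                    p = match_params(),
                                    include_same_primer = FALSE) {
  fwd <- as_bases(forward, "forward primer")
  rev_ <- as_bases(reverse, "reverse primer")
  stopifnot(max_product_length > 0)
  sites <- list(forward = find_binding_sites(fwd, template, p),
                reverse = find_binding_sites(rev_, template, p))
  combos <- list(c("forward", "reverse"))
  if (include_same_primer) {
    combos <- c(combos, list(c("forward", "forward"), c("reverse", "reverse")))
  }
  out <- NULL
  for (cb in combos) {
    fs <- sites[[cb[1]]]; fs <- fs[fs$strand == "+", , drop = FALSE]
    rs <- sites[[cb[2]]]; rs <- rs[rs$strand == "-", , drop = FALSE]
    if (nrow(fs) == 0L || nrow(rs) == 0L) next
    grid <- expand.grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
    len <- rs$end[grid$r] - fs$start[grid$f] + 1L
    keep <- len > 0L & len <= max_product_length
    if (!any(keep)) next
    out <- rbind(out, data.frame(
      template_id = fs$template_id[grid$f[keep]],
      forward_primer = cb[1], reverse_primer = cb[2],
      forward_start = fs$start[grid$f[keep]],
      forward_end = fs$end[grid$f[keep]],
      forward_mismatches = fs$mismatches[grid$f[keep]],
      reverse_start = rs$start[grid$r[keep]],
      reverse_end = rs$end[grid$r[keep]],
      reverse_mismatches = rs$mismatches[grid$r[keep]],
      product_length = len[keep],
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(template_id = character(), forward_primer = character(),
                      reverse_primer = character(), forward_start = integer(),
                      forward_end = integer(), forward_mismatches = integer(),
                      reverse_start = integer(), reverse_end = integer(),
                      reverse_mismatches = integer(), product_length = integer(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(out$forward_start, out$forward_end, out$reverse_start,
                 out$reverse_end, sep = ":")
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$forward_start, out$reverse_end), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "secondary_products") <- nrow(out) > 1L
  out
}
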