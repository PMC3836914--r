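# Generation and evaluation of primer candidates and candidate pairs,
# including long/chimeric primers. Enumeration is exhaustive within the
# window (windows in practice are <= ~1000 bases, so this is tractable and
# deterministic); long candidates flow through exactly the same dimer /
# thermo / binding code paths as short ones.

MAX_PRIMER_LENGTH <- 120L

#' Candidate generation constraints
#'
#' @param window_start,window_end 1-based closed bounds of the template
#'   region candidates may occupy.
#' @param length_min,length_max candidate length range in bases.
#' @param length_optimum preferred length (defaults to the midpoint);
#'   scored, not filtered.
#' @param gc_min,gc_max hard GC-fraction bounds (defaults 0 and 1).
#' @param forbid_c,forbid_g reject candidates containing C (resp. G), for
#'   no-C / no-G designs.
#' @param forbid_n reject candidates containing N (default TRUE).
#' @param excluded_motifs candidates containing any of these substrings are
#'   rejected.
#' @return an object of class \code{generation_spec}.
#' @export
generation_spec <- function(window_start, window_end,
                            length_min = 18L, length_max = 23L,
                            length_optimum = NULL,
                            gc_min = 0, gc_max = 1,
                            forbid_c = FALSE, forbid_g = FALSE,
                            forbid_n = TRUE,
                            excluded_motifs = character()) {
  stopifnot(window_start >= 1L, window_end >= window_start,
            length_min >= 1L, length_max <= MAX_PRIMER_LENGTH,
            length_min <= length_max,
            gc_min >= 0, gc_max <= 1, gc_min <= gc_max)
  if (is.null(length_optimum)) {
    length_optimum <- as.integer(round((length_min + length_max) / 2))
  }
  stopifnot(length_min <= length_optimum, length_optimum <= length_max)
  excluded_motifs <- vapply(excluded_motifs, validate_bases, character(1),
                            what = "excluded motif", USE.NAMES = FALSE)
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 length_optimum = as.integer(length_optimum),
                 gc_min = gc_min, gc_max = gc_max,
                 forbid_c = isTRUE(forbid_c), forbid_g = isTRUE(forbid_g),
                 forbid_n = isTRUE(forbid_n),
                 excluded_motifs = excluded_motifs),
            class = "generation_spec")
}

#' Bundle of analysis parameters used when evaluating candidates
#'
#' @param tm a \code{tm_params} object.
#' @param dimer a \code{dimer_params} object.
#' @param match a \code{match_params} object.
#' @param preferred_tm preferred annealing temperature in degrees C
#'   (default 60), used for penalty normalisation in selection.
#' @param preferred_gc preferred GC fraction (default 0.5).
#' @return an object of class \code{design_config}.
#' @export
design_config <- function(tm = tm_params(), dimer = dimer_params(),
                          match = match_params(),
                          preferred_tm = 60, preferred_gc = 0.5) {
  stopifnot(inherits(tm, "tm_params"), inherits(dimer, "dimer_params"),
            inherits(match, "match_params"))
  structure(list(tm = tm, dimer = dimer, match = match,
                 preferred_tm = preferred_tm, preferred_gc = preferred_gc),
            class = "design_config")
}

.candidate_filter <- function(bases, spec) {
  keep <- rep(TRUE, length(bases))
  if (spec$forbid_n) keep <- keep & !grepl("N", bases, fixed = TRUE)
  if (spec$forbid_c) keep <- keep & !grepl("C", bases, fixed = TRUE)
  if (spec$forbid_g) keep <- keep & !grepl("G", bases, fixed = TRUE)
  for (motif in spec$excluded_motifs) {
    keep <- keep & !grepl(motif, bases, fixed = TRUE)
  }
  if (spec$gc_min > 0 || spec$gc_max < 1) {
    gc <- vapply(bases, gc_content, numeric(1), USE.NAMES = FALSE)
    keep <- keep & gc >= spec$gc_min & gc <= spec$gc_max
  }
  keep
}

#' Enumerate primer candidates in a template window
#'
#' Exhaustively enumerates every substring fully inside the window with
#' length in \code{[length_min, length_max]}, applies the spec's hard
#' sequence filters, and returns the survivors in deterministic order
#' (start, then length). For \code{orientation = "reverse"} the candidate
#' bases are the reverse complement of the template slice (the primer as it
#' would be synthesised); start/length still refer to the plus-strand slice.
#'
#' @param template \code{dna_seq} or DNA string.
#' @param spec a \code{generation_spec}.
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @return data.frame with columns \code{bases}, \code{start}, \code{length},
#'   \code{orientation}. A window smaller than \code{length_min} yields an
#'   empty frame with attribute \code{status}.
#' @export
generate_candidates <- function(template, spec,
                                orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  tb <- as_bases(template, "template")
  stopifnot(inherits(spec, "generation_spec"))
  if (spec$window_end > nchar(tb)) {
    stop("generation window extends beyond the template", call. = FALSE)
  }
  empty <- data.frame(bases = character(), start = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  window_len <- spec$window_end - spec$window_start + 1L
  if (window_len < spec$length_min) {
    attr(empty, "status") <- "window smaller than length_min"
    return(empty)
  }
  rows <- list()
  for (L in seq.int(spec$length_min, min(spec$length_max, window_len))) {
    starts <- seq.int(spec$window_start, spec$window_end - L + 1L)
    slice <- substring(tb, starts, starts + L - 1L)
    bases <- if (orientation == "reverse") {
      vapply(slice, reverse_complement, character(1), USE.NAMES = FALSE)
    } else slice
    rows[[length(rows) + 1L]] <-
      data.frame(bases = bases, start = starts, length = L,
                 orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length), , drop = FALSE]
  out <- out[.candidate_filter(out$bases, spec), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}

#' Evaluate candidate characteristics
#'
#' Fills GC fraction, annealing temperature (via the configured method),
#' hairpin and self-dimer scores, and -- optionally -- binding-site counts
#' against the template and any background sequences. Evaluation is
#' idempotent: re-running on its own output reproduces it exactly.
#'
#' @param cands candidate data.frame from \code{generate_candidates} (or
#'   \code{chimeric_primer}).
#' @param template \code{dna_seq} or DNA string the candidates came from.
#' @param background optional list of \code{dna_seq} (e.g. a genome) to count
#'   secondary binding against.
#' @param config a \code{design_config}.
#' @param count_binding compute binding-site counts (the expensive step;
#'   default TRUE). Skipped columns are filled with NA.
#' @return the input frame with columns \code{gc}, \code{tm},
#'   \code{hairpin}, \code{self_dimer}, \code{binding_count} and (when
#'   background is given) \code{background_binding_count} added.
#' @export
evaluate_candidates <- function(cands, template, background = NULL,
                                config = design_config(),
                                count_binding = TRUE) {
  stopifnot(is.data.frame(cands), inherits(config, "design_config"))
  n <- nrow(cands)
  cands$gc <- vapply(cands$bases, gc_content, numeric(1), USE.NAMES = FALSE)
  cands$tm <- vapply(cands$bases, melting_temperature, numeric(1),
                     params = config$tm, USE.NAMES = FALSE)
  cands$hairpin <- vapply(cands$bases, function(b)
    hairpin_score(b, config$dimer)$score, numeric(1), USE.NAMES = FALSE)
  cands$self_dimer <- vapply(cands$bases, function(b)
    self_dimer_score(b, config$dimer)$score, numeric(1), USE.NAMES = FALSE)
  if (count_binding) {
    cands$binding_count <- vapply(cands$bases, count_binding_sites,
                                  integer(1), template = template,
                                  p = config$match, USE.NAMES = FALSE)
    if (!is.null(background)) {
      if (inherits(background, "dna_seq")) background <- list(background)
      cands$background_binding_count <- vapply(cands$bases, function(b) {
        sum(vapply(background, function(g)
          count_binding_sites(b, g, config$match), integer(1)))
      }, integer(1), USE.NAMES = FALSE)
    }
  } else {
    cands$binding_count <- rep(NA_integer_, n)
  }
  cands
}

#' Pair forward and reverse candidates
#'
#' Cartesian pairing of evaluated forward and reverse candidates, filtered
#' to \code{product_min <= product_length <= product_max}, with pair-level
#' characteristics (pair-dimer score, Tm / GC / length differences) filled.
#'
#' @param forwards,reverses evaluated candidate data.frames; reverses must
#'   be reverse-orientation candidates downstream of the forwards.
#' @param product_min,product_max product-length bounds in bases.
#' @param config a \code{design_config}.
#' @return data.frame with \code{forward_}/\code{reverse_}-prefixed candidate
#'   columns plus \code{product_length}, \code{pair_dimer},
#'   \code{tm_difference}, \code{gc_difference}, \code{length_difference}.
#' @export
make_pairs <- function(forwards, reverses, product_min, product_max,
                       config = design_config()) {
  stopifnot(is.data.frame(forwards), is.data.frame(reverses),
            product_min <= product_max)
  empty <- data.frame()
  if (nrow(forwards) == 0L || nrow(reverses) == 0L) return(empty)
  grid <- expand.grid(f = seq_len(nrow(forwards)), r = seq_len(nrow(reverses)))
  rev_end <- reverses$start[grid$r] + reverses$length[grid$r] - 1L
  product_length <- rev_end - forwards$start[grid$f] + 1L
  keep <- product_length >= product_min & product_length <= product_max &
    forwards$start[grid$f] + forwards$length[grid$f] - 1L < reverses$start[grid$r]
  if (!any(keep)) return(empty)
  grid <- grid[keep, , drop = FALSE]
  product_length <- product_length[keep]
  pick <- function(df, idx, prefix) {
    out <- df[idx, , drop = FALSE]
    names(out) <- paste0(prefix, names(out))
    rownames(out) <- NULL
    out
  }
  out <- cbind(pick(forwards, grid$f, "forward_"),
               pick(reverses, grid$r, "reverse_"))
  out$product_length <- product_length
  out$pair_dimer <- mapply(function(a, b)
    pair_dimer_score(a, b, config$dimer)$score,
    out$forward_bases, out$reverse_bases, USE.NAMES = FALSE)
  out$tm_difference <- abs(out$forward_tm - out$reverse_tm)
  out$gc_difference <- abs(out$forward_gc - out$reverse_gc)
  out$length_difference <- abs(out$forward_length - out$reverse_length)
  out <- out[order(out$forward_start, out$reverse_start,
                   out$forward_length, out$reverse_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a chimeric primer candidate
#'
#' Concatenates two segments (e.g. a marker-gene primer and a template tail)
#' into one long candidate that flows through every analysis operation
#' (dimer, thermo, binding) unchanged. Combined length is capped at 120
#' bases.
#'
#' @param head,tail DNA strings; \code{tail} may be empty.
#' @return a one-row candidate data.frame (start is NA: a chimeric primer
#'   has no single template locus).
#' @export
chimeric_primer <- function(head, tail = "") {
  hb <- as_bases(head, "head")
  tb <- as_bases(tail, "tail", allow_empty = TRUE)
  bases <- paste0(hb, tb)
  if (nchar(bases) > MAX_PRIMER_LENGTH) {
    stop(sprintf("chimeric primer of %d bases exceeds the %d-base limit",
                 nchar(bases), MAX_PRIMER_LENGTH), call. = FALSE)
  }
  data.frame(bases = bases, start = NA_integer_, length = nchar(bases),
             orientation = "forward", stringsAsFactors = FALSE)
}
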