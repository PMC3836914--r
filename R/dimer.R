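# Rule-based hairpin / self-dimer / pair-dimer detection. A window of
# user-definable length at the 3' end of the primer (the "tail") is slid,
# ungapped and antiparallel, against the partner sequence (or, for hairpins,
# against the primer's own 5' portion); Watson-Crick complements score
# weight_gc per G:C and weight_at per A:T, and the maximum over all offsets
# is reported, capped at max_score. Restricting scoring to the 3' tail is
# what lets the same rule work for primers from ~10 up to >100 bases.

#' Dimer / hairpin scoring parameters
#'
#' @param tail_length number of 3'-terminal bases scored (default 12).
#' @param weight_gc score per complementary G:C pair (default 2).
#' @param weight_at score per complementary A:T pair (default 1).
#' @param max_score cap on the reported score
#'   (default \code{weight_gc * tail_length}, a fully G/C-complementary tail).
#' @param hairpin_min_loop minimum unpaired loop length for hairpin folds
#'   (default 3).
#' @param threshold rejection score used by the selection layer
#'   (default \code{0.55 * max_score}).
#' @return an object of class \code{dimer_params}.
#' @export
dimer_params <- function(tail_length = 12L, weight_gc = 2, weight_at = 1,
                         max_score = weight_gc * tail_length,
                         hairpin_min_loop = 3L,
                         threshold = 0.55 * max_score) {
  stopifnot(tail_length >= 1L, weight_gc > 0, weight_at > 0,
            max_score >= weight_gc, threshold <= max_score,
            hairpin_min_loop >= 0L)
  structure(list(tail_length = as.integer(tail_length),
                 weight_gc = weight_gc, weight_at = weight_at,
                 max_score = max_score,
                 hairpin_min_loop = as.integer(hairpin_min_loop),
                 threshold = threshold),
            class = "dimer_params")
}

dimer_result <- function(score, offset, matched_pairs, status = "ok") {
  structure(list(score = score, offset = offset,
                 matched_pairs = matched_pairs, status = status),
            class = "dimer_result")
}

#' @export
print.dimer_result <- function(x, ...) {
  cat(sprintf("<dimer_result> score %g (%d pairs at offset %d)%s\n",
              x$score, x$matched_pairs, x$offset,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

# per-base pairing weight of the tail bases (N contributes 0)
.tail_weights <- function(tail_codes, p) {
  w <- c(p$weight_at, p$weight_gc, p$weight_gc, p$weight_at, 0)
  w[tail_codes]
}

# Slide tail (3' window of a primer, 5'->3') along target in antiparallel
# orientation: tail base i pairs with target base j where j decreases as i
# increases. Equivalently, compare the tail against the reverse complement
# of the target at every ungapped offset (partial overlaps included).
.slide_score <- function(tail_codes, target_codes, p) {
  lt <- length(tail_codes)
  rc_target <- rev(.COMP_CODE[target_codes])
  lb <- length(rc_target)
  w <- .tail_weights(tail_codes, p)
  best <- list(score = 0, offset = 0L, matched_pairs = 0L)
  for (k in seq.int(-(lt - 1L), lb - 1L)) {
    i <- seq_len(lt)
    j <- i + k
    keep <- j >= 1L & j <= lb
    if (!any(keep)) next
    hit <- tail_codes[i[keep]] == rc_target[j[keep]] & tail_codes[i[keep]] != .N_CODE
    sc <- sum(w[i[keep]][hit])
    if (sc > best$score) {
      best <- list(score = sc, offset = k, matched_pairs = sum(hit))
    }
  }
  best
}

.one_sided_dimer <- function(a, b, p) {
  ac <- encode_dna(a)
  lt <- min(p$tail_length, length(ac))
  tail_codes <- ac[seq.int(length(ac) - lt + 1L, length(ac))]
  .slide_score(tail_codes, encode_dna(b), p)
}

#' Pair-dimer score
#'
#' Scores the 3' tail of each primer against the full length of the other
#' (antiparallel, ungapped, every offset) and reports the larger of the two,
#' capped at \code{max_score}.
#'
#' @param a,b primer DNA strings (or \code{dna_seq}), non-empty.
#' @param p a \code{dimer_params} object.
#' @return a \code{dimer_result} with fields \code{score}, \code{offset},
#'   \code{matched_pairs}.
#' @export
pair_dimer_score <- function(a, b, p = dimer_params()) {
  a <- as_bases(a, "primer a"); b <- as_bases(b, "primer b")
  r1 <- .one_sided_dimer(a, b, p)
  r2 <- .one_sided_dimer(b, a, p)
  best <- if (r2$score > r1$score) r2 else r1
  dimer_result(min(best$score, p$max_score), best$offset, best$matched_pairs)
}

#' Self-dimer score
#'
#' \code{pair_dimer_score(a, a, p)} semantics: the primer's own 3' tail
#' scored against a second copy of itself.
#'
#' @inheritParams pair_dimer_score
#' @return a \code{dimer_result}.
#' @export
self_dimer_score <- function(a, p = dimer_params()) {
  a <- as_bases(a, "primer")
  r <- .one_sided_dimer(a, a, p)
  dimer_result(min(r$score, p$max_score), r$offset, r$matched_pairs)
}

#' Hairpin score
#'
#' Folds the primer's 3' tail back onto its own 5' portion, antiparallel and
#' ungapped, counting only base pairs separated from the tail by at least
#' \code{hairpin_min_loop} unpaired loop bases. Sequences too short to fold
#' (length < tail_length + hairpin_min_loop + 1) get score 0 with status
#' \code{"too short"} rather than an error.
#'
#' @inheritParams pair_dimer_score
#' @return a \code{dimer_result}; \code{status} is \code{"ok"} or
#'   \code{"too short"}.
#' @export
hairpin_score <- function(a, p = dimer_params()) {
  a <- as_bases(a, "primer")
  n <- nchar(a)
  if (n < p$tail_length + p$hairpin_min_loop + 1L) {
    return(dimer_result(0, 0L, 0L, status = "too short"))
  }
  codes <- encode_dna(a)
  lt <- p$tail_length
  tail_pos <- seq.int(n - lt + 1L, n)          # 1-based positions of the tail
  tail_codes <- codes[tail_pos]
  w <- .tail_weights(tail_codes, p)
  best <- list(score = 0, offset = 0L, matched_pairs = 0L)
  # anchor q: tail base i (position tail_pos[i]) pairs upstream position q - i + 1
  for (q in seq_len(n)) {
    i <- seq_len(lt)
    partner <- q - i + 1L
    keep <- partner >= 1L &
      (tail_pos - partner - 1L) >= p$hairpin_min_loop
    if (!any(keep)) next
    hit <- codes[partner[keep]] == .COMP_CODE[tail_codes[keep]] &
      tail_codes[keep] != .N_CODE
    sc <- sum(w[keep][hit])
    if (sc > best$score) {
      best <- list(score = sc, offset = q, matched_pairs = sum(hit))
    }
  }
  dimer_result(min(best$score, p$max_score), best$offset, best$matched_pairs)
}
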