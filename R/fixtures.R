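# Seeded synthetic-data generators. Every fixture is reproducible from
# (seed, arguments) and carries a manifest of its ground truth, so tests
# never need external data. If the random background happens to contain an
# accidental binding site, the background is re-drawn (not masked), keeping
# the manifest's expected-site set exact.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deterministic substitution: each base to a fixed different base
.substitute_base <- function(base) {
  c(A = "C", C = "G", G = "T", T = "A", N = "A")[[base]]
}

# positions (1-based, within the plant) to mutate
.mismatch_positions <- function(len, k, spacing) {
  if (k == 0L) return(integer())
  if (spacing == "even") {
    unique(round(seq(2L, len - 1L, length.out = k)))
  } else {                       # clustered: a consecutive internal block
    seq.int(2L, 1L + k)
  }
}

#' Synthetic template with planted primer binding sites
#'
#' Draws a uniform-random background from the seed and inserts each plant
#' (verbatim, or carrying a requested number of clustered or evenly spaced
#' substitutions; on the minus strand the reverse complement of the mutated
#' primer is inserted). The manifest records the exact expected binding
#' sites; the background is verified free of accidental matches of any
#' planted primer (at \code{verify$max_mismatches}, pure Hamming, both
#' strands) and re-drawn from a derived seed if necessary.
#'
#' @param length template length in bases.
#' @param seed integer seed.
#' @param plants list of plants, each a list with \code{sequence}
#'   (the primer), \code{position} (1-based start), and optional
#'   \code{strand} ("+"/"-", default "+"), \code{mismatches} (default 0),
#'   \code{spacing} ("even" or "clustered", default "even").
#' @param verify \code{match_params} used for the accidental-match check
#'   (default: pure Hamming with 2 mismatches, both strands).
#' @param max_redraws attempts before giving up (default 50).
#' @return list with \code{sequence} (a \code{dna_seq}) and \code{manifest}
#'   (data.frame of expected sites: primer, start, end, strand, mismatches).
#' @export
make_template <- function(length, seed, plants = list(),
                          verify = match_params(max_mismatches = 2,
                                                three_prime_exact = 0L),
                          max_redraws = 50L) {
  stopifnot(length >= 1L)
  for (p in plants) {
    stopifnot(!is.null(p$sequence), !is.null(p$position))
    if (p$position + nchar(p$sequence) - 1L > length) {
      stop("plant does not fit in the template", call. = FALSE)
    }
  }
  if (length(plants) > 1L) {
    starts <- vapply(plants, function(p) p$position, numeric(1))
    ends <- vapply(plants, function(p) p$position + nchar(p$sequence) - 1L,
                   numeric(1))
    o <- order(starts)
    if (any(starts[o][-1L] <= ends[o][-length(ends)])) {
      stop("plants overlap", call. = FALSE)
    }
  }

  build <- function(attempt) {
    bg <- with_seed(seed + (attempt - 1L) * 97L, random_dna(length))
    chars <- strsplit(bg, "", fixed = TRUE)[[1L]]
    manifest <- list()
    for (p in plants) {
      strand <- if (is.null(p$strand)) "+" else p$strand
      k <- if (is.null(p$mismatches)) 0L else as.integer(p$mismatches)
      spacing <- if (is.null(p$spacing)) "even" else p$spacing
      primer <- validate_bases(p$sequence, "plant sequence")
      mut <- primer
      pos <- .mismatch_positions(nchar(primer), k, spacing)
      if (length(pos) > 0L) {
        mchars <- strsplit(mut, "", fixed = TRUE)[[1L]]
        mchars[pos] <- vapply(mchars[pos], .substitute_base, character(1))
        mut <- paste(mchars, collapse = "")
      }
      inserted <- if (strand == "+") mut else reverse_complement(mut)
      span <- seq.int(p$position, p$position + nchar(primer) - 1L)
      chars[span] <- strsplit(inserted, "", fixed = TRUE)[[1L]]
      manifest[[length(manifest) + 1L]] <- data.frame(
        primer = primer, start = p$position,
        end = p$position + nchar(primer) - 1L, strand = strand,
        mismatches = length(pos), spacing = spacing,
        stringsAsFactors = FALSE)
    }
    manifest <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(primer = character(), start = integer(), end = integer(),
                 strand = character(), mismatches = integer(),
                 spacing = character(), stringsAsFactors = FALSE)
    list(sequence = dna_sequence(paste(chars, collapse = ""),
                                 id = sprintf("template_seed%d", seed)),
         manifest = manifest)
  }

  for (attempt in seq_len(max_redraws)) {
    fx <- build(attempt)
    ok <- TRUE
    for (primer in unique(fx$manifest$primer)) {
      found <- find_binding_sites(primer, fx$sequence, verify)
      expected <- fx$manifest[fx$manifest$primer == primer &
                                fx$manifest$mismatches <=
                                  .resolve_max_mm(verify, nchar(primer)), ,
                              drop = FALSE]
      if (nrow(found) != nrow(expected) ||
          !all(found$start == sort(expected$start))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(fx)
  }
  stop("could not draw a background free of accidental binding sites",
       call. = FALSE)
}

#' Synthetic sequencing read with a centred microsatellite
#'
#' Builds a read (default 500 bases, echoing typical long-read lengths)
#' with a tandem repeat in the middle and clean -- or deliberately
#' contaminated -- flanks. The background is re-drawn until the strict-mode
#' repeat finder reports exactly the planted repeat, so the manifest is
#' exact ground truth.
#'
#' @param length read length (default 500).
#' @param unit repeat unit (2-4 bases).
#' @param unit_count number of tandem copies.
#' @param seed integer seed.
#' @param n_run optional list(offset, length): plant a run of Ns starting
#'   \code{offset} bases downstream of the repeat.
#' @param flank_repeat optional list(unit, count, side = "upstream" or
#'   "downstream"): plant a contaminating repeat in a flank.
#' @param strict \code{ssr_params} the manifest is verified against.
#' @param max_redraws attempts before giving up.
#' @return list with \code{sequence} (a \code{dna_seq}) and \code{manifest}
#'   (list: repeat_start, repeat_end, unit, contaminants, feasible flags).
#' @export
make_ssr_read <- function(length = 500L, unit = "CAG", unit_count = 9L,
                          seed = 1L, n_run = NULL, flank_repeat = NULL,
                          strict = ssr_params("strict"),
                          max_redraws = 100L) {
  unit <- validate_bases(unit, "repeat unit")
  rep_len <- nchar(unit) * unit_count
  stopifnot(rep_len + 2L * 60L <= length)
  rep_start <- (length - rep_len) %/% 2L + 1L
  rep_end <- rep_start + rep_len - 1L

  for (attempt in seq_len(max_redraws)) {
    chars <- with_seed(seed + (attempt - 1L) * 101L, {
      strsplit(random_dna(length), "", fixed = TRUE)[[1L]]
    })
    chars[seq.int(rep_start, rep_end)] <-
      strsplit(strrep(unit, unit_count), "", fixed = TRUE)[[1L]]
    if (!is.null(flank_repeat)) {
      fr <- strrep(flank_repeat$unit, flank_repeat$count)
      side <- if (is.null(flank_repeat$side)) "upstream" else flank_repeat$side
      fr_start <- if (side == "upstream") rep_start - nchar(fr) - 10L else
        rep_end + 11L
      stopifnot(fr_start >= 1L, fr_start + nchar(fr) - 1L <= length)
      chars[seq.int(fr_start, fr_start + nchar(fr) - 1L)] <-
        strsplit(fr, "", fixed = TRUE)[[1L]]
    }
    if (!is.null(n_run)) {
      ns <- rep_end + n_run$offset
      stopifnot(ns >= 1L, ns + n_run$length - 1L <= length)
      chars[seq.int(ns, ns + n_run$length - 1L)] <- "N"
    }
    read <- dna_sequence(paste(chars, collapse = ""),
                         id = sprintf("read_seed%d", seed))
    hits <- find_microsatellites(read, strict)
    planted <- hits$start == rep_start & hits$end == rep_end &
      hits$unit == unit
    extra_expected <- !is.null(flank_repeat) &&
      nchar(flank_repeat$unit) * flank_repeat$count >= strict$min_total_length
    ok <- sum(planted) == 1L && nrow(hits) == (1L + extra_expected)
    if (ok) {
      return(list(sequence = read,
                  manifest = list(repeat_start = rep_start,
                                  repeat_end = rep_end, unit = unit,
                                  unit_count = unit_count,
                                  n_run = n_run, flank_repeat = flank_repeat,
                                  clean = is.null(n_run) &&
                                    is.null(flank_repeat))))
    }
  }
  stop("could not draw a read whose repeat content matches the manifest",
       call. = FALSE)
}
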