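# Microsatellite (SSR) detection and flanking-primer design. A built-in
# tandem-repeat finder (match +1 / mismatch -6 extension scoring, in the
# style of classic repeat scanners) runs in a strict mode to find reportable
# repeats and in a relaxed mode, called recursively during primer design, to
# make sure the primers and the flanking regions up to the repeat contain no
# other microsatellite.

#' Repeat-finder parameters
#'
#' @param mode \code{"strict"} (reportable, high-scoring repeats) or
#'   \code{"relaxed"} (the permissive contamination screen used inside
#'   primer design).
#' @param unit_lengths repeat-unit lengths considered (default 2:4).
#' @param min_total_length minimum repeat span in bases (strict default 21,
#'   relaxed default 12).
#' @param match_score score per base matching the base one unit upstream
#'   (default +1).
#' @param mismatch_penalty score per mismatching base (default -6).
#' @param min_score minimum extension score to report (strict default 15,
#'   relaxed default 8).
#' @return an object of class \code{ssr_params}.
#' @export
ssr_params <- function(mode = c("strict", "relaxed"),
                       unit_lengths = 2:4,
                       min_total_length = NULL,
                       match_score = 1, mismatch_penalty = -6,
                       min_score = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_total_length)) {
    min_total_length <- if (mode == "strict") 21L else 12L
  }
  if (is.null(min_score)) min_score <- if (mode == "strict") 15 else 8
  stopifnot(all(unit_lengths >= 1L), min_total_length >= 1L,
            match_score > 0, mismatch_penalty < 0)
  structure(list(mode = mode, unit_lengths = as.integer(sort(unit_lengths)),
                 min_total_length = as.integer(min_total_length),
                 match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 min_score = min_score),
            class = "ssr_params")
}

# TRUE if unit is itself a tandem repetition of a shorter unit (e.g. "ATAT")
.is_periodic_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        identical(strrep(substr(unit, 1L, d), u %/% d), unit)) return(TRUE)
  }
  FALSE
}

#' Find microsatellites in a read
#'
#' Scans every start position and unit length; from each seed unit, extends
#' rightward comparing each base to the base one unit upstream
#' (match \code{+1}, mismatch \code{-6}) and keeps the extension endpoint
#' with the maximal cumulative score. Repeats meeting the mode's span and
#' score thresholds are reported as maximal non-overlapping regions,
#' resolved deterministically left to right (ties: higher score, then
#' shorter unit).
#'
#' @param read \code{dna_seq} or DNA string.
#' @param p an \code{ssr_params} object.
#' @return data.frame with columns \code{read_id}, \code{start}, \code{end}
#'   (1-based closed), \code{unit}, \code{unit_count}, \code{total_length},
#'   \code{score}.
#' @export
find_microsatellites <- function(read, p = ssr_params()) {
  rb <- as_bases(read, "read")
  rid <- seq_id(read, "read")
  chars <- strsplit(rb, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cand <- list()
  for (u in p$unit_lengths) {
    if (2L * u > n) next
    # score[j] for j > u: +1 if chars[j] == chars[j - u], else mismatch
    eq <- chars[seq.int(u + 1L, n)] == chars[seq.int(1L, n - u)] &
      chars[seq.int(u + 1L, n)] != "N"
    step <- ifelse(eq, p$match_score, p$mismatch_penalty)
    for (i in seq_len(n - 2L * u + 1L)) {
      unit <- substr(rb, i, i + u - 1L)
      if (grepl("N", unit, fixed = TRUE) || .is_periodic_unit(unit)) next
      # seed must repeat at least once before extension is worth scoring
      if (!all(eq[seq.int(i, i + u - 1L)])) next
      cum <- cumsum(step[seq.int(i, n - u)])
      best_j <- which.max(cum)
      score <- cum[best_j]
      end <- u + i + best_j - 1L        # template position of last scored base
      total_length <- end - i + 1L
      if (total_length < p$min_total_length || score < p$min_score) next
      cand[[length(cand) + 1L]] <- data.frame(
        read_id = rid, start = i, end = end, unit = unit,
        unit_count = total_length %/% u, total_length = total_length,
        score = score, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(read_id = character(), start = integer(),
                      end = integer(), unit = character(),
                      unit_count = integer(), total_length = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -cand$score, nchar(cand$unit)), , drop = FALSE]
  taken_end <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > taken_end) {
      keep[i] <- TRUE
      taken_end <- cand$end[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flanking-primer design configuration
#'
#' Defaults encode the printed constraint set for microsatellite-marker
#' design: primer length 20-30 bases (for economy), product 80-300 bases,
#' N-free products, matched GC content, Tm near a preferred value, no
#' repeat-unit or microsatellite contamination, and unique within-read
#' binding.
#'
#' @param primer_length_min,primer_length_max primer length bounds.
#' @param product_min,product_max product-length bounds in bases.
#' @param preferred_tm preferred annealing temperature in degrees C
#'   (default 60; a configurable application parameter).
#' @param tm_tolerance maximum |Tm - preferred_tm| per primer (default 5).
#' @param gc_tolerance maximum forward/reverse GC difference (default 0.1).
#' @param tm_method annealing-temperature method (default the
#'   SantaLucia-parameterised nearest-neighbor calculation).
#' @param relaxed \code{ssr_params} used for the recursive contamination
#'   screen of primers and flanks.
#' @param shortlist per-side cap on candidates carried into pairing after
#'   single-primer filtering (default 25; keeps design fast).
#' @param config a \code{design_config} for evaluation (its \code{tm} field
#'   is rebuilt from \code{tm_method}).
#' @return an object of class \code{ssr_design_config}.
#' @export
ssr_design_config <- function(primer_length_min = 20L, primer_length_max = 30L,
                              product_min = 80L, product_max = 300L,
                              preferred_tm = 60, tm_tolerance = 5,
                              gc_tolerance = 0.1,
                              tm_method = "santalucia_nn",
                              relaxed = ssr_params("relaxed"),
                              shortlist = 25L,
                              config = design_config()) {
  config$tm <- tm_params(method = tm_method)
  config$preferred_tm <- preferred_tm
  structure(list(primer_length_min = as.integer(primer_length_min),
                 primer_length_max = as.integer(primer_length_max),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 preferred_tm = preferred_tm, tm_tolerance = tm_tolerance,
                 gc_tolerance = gc_tolerance, relaxed = relaxed,
                 shortlist = as.integer(shortlist), config = config),
            class = "ssr_design_config")
}

# >= 2 tandem copies of the unit (either strand orientation) inside a primer
.contains_unit_tandem <- function(bases, unit) {
  grepl(strrep(unit, 2L), bases, fixed = TRUE) ||
    grepl(strrep(reverse_complement(unit), 2L), bases, fixed = TRUE)
}

.ssr_single_ok <- function(bases, read, unit, cfg) {
  if (.contains_unit_tandem(bases, unit)) return(FALSE)
  if (nrow(find_microsatellites(bases, cfg$relaxed)) > 0L) return(FALSE)
  count_binding_sites(bases, read, cfg$config$match) == 1L
}

#' Design flanking primers for one microsatellite
#'
#' Generates forward candidates upstream and reverse candidates downstream
#' of the repeat and returns the best pair satisfying the full constraint
#' set: primer length 20-30; product 80-300 bases spanning the repeat;
#' product free of Ns; matched GC and Tm near the preferred value; no
#' tandem copy of the repeat unit in a primer; no relaxed-mode
#' microsatellite in a primer or in the flanks between the primers and the
#' repeat; exactly one binding site per primer within the read. Absence of
#' a feasible pair is a legitimate outcome (returns NULL).
#'
#' @param read the \code{dna_seq} the repeat was found in.
#' @param ms one row of \code{\link{find_microsatellites}} output (or a list
#'   with \code{start}, \code{end}, \code{unit}).
#' @param cfg an \code{ssr_design_config}.
#' @return a one-row pair data.frame (see \code{\link{make_pairs}}) or NULL.
#' @export
design_flanking_primers <- function(read, ms, cfg = ssr_design_config()) {
  rb <- as_bases(read, "read")
  n <- nchar(rb)
  ms_start <- as.integer(ms$start); ms_end <- as.integer(ms$end)
  unit <- as.character(ms$unit)
  stopifnot(ms_start >= 1L, ms_end <= n, ms_start <= ms_end)
  if (ms_start - 1L < cfg$primer_length_min ||
      n - ms_end < cfg$primer_length_min) return(NULL)

  up_spec <- generation_spec(1L, ms_start - 1L,
                             length_min = cfg$primer_length_min,
                             length_max = cfg$primer_length_max)
  down_spec <- generation_spec(ms_end + 1L, n,
                               length_min = cfg$primer_length_min,
                               length_max = cfg$primer_length_max)
  fwd <- generate_candidates(rb, up_spec, orientation = "forward")
  rev <- generate_candidates(rb, down_spec, orientation = "reverse")
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(NULL)

  # product-span bound: drop candidates that cannot fall inside any product
  fwd <- fwd[ms_end - fwd$start + 1L + cfg$primer_length_min <= cfg$product_max, ,
             drop = FALSE]
  rev <- rev[rev$start + rev$length - 1L - ms_start + 1L +
               cfg$primer_length_min <= cfg$product_max, , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(NULL)

  screen <- function(df) {
    keep <- vapply(df$bases, .ssr_single_ok, logical(1), read = rb,
                   unit = unit, cfg = cfg, USE.NAMES = FALSE)
    df[keep, , drop = FALSE]
  }
  eval_side <- function(df) {
    # Tm is cheap; compute it alone, filter and shortlist before the
    # dimer/binding evaluation of the survivors
    tm <- vapply(df$bases, melting_temperature, numeric(1),
                 params = cfg$config$tm, USE.NAMES = FALSE)
    df <- df[abs(tm - cfg$preferred_tm) <= cfg$tm_tolerance, , drop = FALSE]
    if (nrow(df) == 0L) return(df)
    tm <- tm[abs(tm - cfg$preferred_tm) <= cfg$tm_tolerance]
    df <- utils::head(df[order(abs(tm - cfg$preferred_tm)), , drop = FALSE],
                      cfg$shortlist)
    df <- screen(df)
    if (nrow(df) == 0L) return(df)
    evaluate_candidates(df, rb, config = cfg$config, count_binding = FALSE)
  }
  # the flank between a primer and the repeat depends on that primer alone,
  # so screen it per candidate rather than per pair
  flank_clean <- function(lo, hi) {
    if (lo > hi) return(TRUE)
    nrow(find_microsatellites(substring(rb, lo, hi), cfg$relaxed)) == 0L
  }
  fwd <- eval_side(fwd); if (nrow(fwd) == 0L) return(NULL)
  fwd <- fwd[vapply(seq_len(nrow(fwd)), function(i)
    flank_clean(fwd$start[i] + fwd$length[i], ms_start - 1L), logical(1)), ,
    drop = FALSE]
  if (nrow(fwd) == 0L) return(NULL)
  rev <- eval_side(rev); if (nrow(rev) == 0L) return(NULL)
  rev <- rev[vapply(seq_len(nrow(rev)), function(i)
    flank_clean(ms_end + 1L, rev$start[i] - 1L), logical(1)), , drop = FALSE]
  if (nrow(rev) == 0L) return(NULL)

  pairs <- make_pairs(fwd, rev, cfg$product_min, cfg$product_max,
                      config = cfg$config)
  if (nrow(pairs) == 0L) return(NULL)

  product_seq <- substring(rb, pairs$forward_start,
                           pairs$reverse_start + pairs$reverse_length - 1L)
  keep <- !grepl("N", product_seq, fixed = TRUE) &
    pairs$gc_difference <= cfg$gc_tolerance
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)

  spec <- selection_spec(list(
    characteristic("pair_dimer", priority = 1),
    characteristic("tm_deviation", priority = 2),
    characteristic("gc_difference", priority = 3),
    characteristic("self_dimer", priority = 4)),
    method = "prioritised_then_multi_objective",
    preferred_tm = cfg$preferred_tm)
  ranked <- sort_candidates(pairs, spec)
  ranked <- ranked[!ranked$rejected, , drop = FALSE]
  if (nrow(ranked) == 0L) return(NULL)
  out <- ranked[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the SSR pipeline over reads
#'
#' For each read: strict-mode repeat detection, then flanking-primer design
#' for each repeat. One output row per repeat with a feasible pair.
#'
#' @param reads list of \code{dna_seq} (e.g. from \code{read_fasta}).
#' @param strict \code{ssr_params} for detection.
#' @param cfg an \code{ssr_design_config}.
#' @return data.frame with read id, repeat unit and span, primer sequences,
#'   Tm, GC and product length.
#' @export
design_ssr_primers <- function(reads, strict = ssr_params("strict"),
                               cfg = ssr_design_config()) {
  if (inherits(reads, "dna_seq")) reads <- list(reads)
  rows <- list()
  for (read in reads) {
    hits <- find_microsatellites(read, strict)
    for (i in seq_len(nrow(hits))) {
      pair <- design_flanking_primers(read, hits[i, ], cfg)
      if (is.null(pair)) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read$id, unit = hits$unit[i],
        repeat_start = hits$start[i], repeat_end = hits$end[i],
        forward_primer = pair$forward_bases,
        reverse_primer = pair$reverse_bases,
        forward_tm = pair$forward_tm, reverse_tm = pair$reverse_tm,
        forward_gc = pair$forward_gc, reverse_gc = pair$reverse_gc,
        product_length = pair$product_length,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(), unit = character(),
                      repeat_start = integer(), repeat_end = integer(),
                      forward_primer = character(), reverse_primer = character(),
                      forward_tm = numeric(), reverse_tm = numeric(),
                      forward_gc = numeric(), reverse_gc = numeric(),
                      product_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
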