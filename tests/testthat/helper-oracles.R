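# Independent oracles, written as direct transliterations of the definitions
# (naive loops, separate parameter transcriptions) so they share no code
# path with the package implementation.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(.ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

random_oligo <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- nearest-neighbor Tm oracle -------------------------------------------
# Full 16-entry stack tables transcribed independently from the published
# parameter sets (dh kcal/mol, ds cal/K/mol), expanded by hand over all 16
# dinucleotides; summation by a plain loop.

.ORACLE_NN <- list(
  breslauer_nn = list(
    dh = c(AA = -9.1, AC = -6.5, AG = -7.8, AT = -8.6,
           CA = -5.8, CC = -11.0, CG = -11.9, CT = -7.8,
           GA = -5.6, GC = -11.1, GG = -11.0, GT = -6.5,
           TA = -6.0, TC = -5.6, TG = -5.8, TT = -9.1),
    ds = c(AA = -24.0, AC = -17.3, AG = -20.8, AT = -23.9,
           CA = -12.9, CC = -26.6, CG = -27.8, CT = -20.8,
           GA = -13.5, GC = -26.7, GG = -26.6, GT = -17.3,
           TA = -16.9, TC = -13.5, TG = -12.9, TT = -24.0),
    sym_ds = -1.3),
  santalucia_nn = list(
    dh = c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9),
    ds = c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2),
    sym_ds = -1.4),
  freier_nn = list(
    dh = c(AA = -6.6, AC = -10.2, AG = -7.6, AT = -5.7,
           CA = -10.5, CC = -12.2, CG = -8.0, CT = -7.6,
           GA = -13.3, GC = -14.2, GG = -12.2, GT = -10.2,
           TA = -8.1, TC = -13.3, TG = -10.5, TT = -6.6),
    ds = c(AA = -18.4, AC = -26.2, AG = -19.2, AT = -15.5,
           CA = -27.8, CC = -29.7, CG = -19.4, CT = -19.2,
           GA = -35.5, GC = -34.9, GG = -29.7, GT = -26.2,
           TA = -22.6, TC = -35.5, TG = -27.8, TT = -18.4),
    sym_ds = -1.4))

oracle_tm_nn <- function(s, method, ct = 5e-8, na = 0.05) {
  tab <- .ORACLE_NN[[method]]
  chars <- strsplit(s, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(chars) - 1)) {
    key <- paste0(chars[i], chars[i + 1])
    dh <- dh + tab$dh[[key]]
    ds <- ds + tab$ds[[key]]
  }
  if (method == "breslauer_nn") {
    ds <- ds + if (any(chars %in% c("G", "C"))) -16.8 else -20.1
  } else if (method == "santalucia_nn") {
    for (end in c(chars[1], chars[length(chars)])) {
      if (end %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
      else { dh <- dh + 0.1; ds <- ds - 2.8 }
    }
  } else {
    ds <- ds - 10.8
  }
  selfcomp <- identical(s, oracle_revcomp(s))
  if (selfcomp) ds <- ds + tab$sym_ds
  x <- if (selfcomp) 1 else 4
  dh * 1000 / (ds + 1.987 * log(ct / x)) - 273.15 + 16.6 * log10(na)
}

# ---- dimer / hairpin oracles ----------------------------------------------
# Antiparallel pairing enumerated as "i + j constant" diagonals.

.oracle_pair_weight <- function(base, wgc, wat) {
  if (base %in% c("G", "C")) wgc else if (base %in% c("A", "T")) wat else 0
}

oracle_tail_vs <- function(a, b, tail_length, wgc = 2, wat = 1) {
  lt <- min(tail_length, nchar(a))
  tc <- strsplit(substring(a, nchar(a) - lt + 1, nchar(a)), "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- 0
  for (const in 2:(lt + length(bc))) {
    sc <- 0
    for (i in seq_len(lt)) {
      j <- const - i
      if (j >= 1 && j <= length(bc) && tc[i] != "N" &&
          bc[j] == .ORACLE_COMP[[tc[i]]]) {
        sc <- sc + .oracle_pair_weight(tc[i], wgc, wat)
      }
    }
    if (sc > best) best <- sc
  }
  best
}

oracle_pair_dimer <- function(a, b, tail_length, wgc = 2, wat = 1, cap = Inf) {
  min(max(oracle_tail_vs(a, b, tail_length, wgc, wat),
          oracle_tail_vs(b, a, tail_length, wgc, wat)), cap)
}

oracle_self_dimer <- function(a, tail_length, wgc = 2, wat = 1, cap = Inf) {
  min(oracle_tail_vs(a, a, tail_length, wgc, wat), cap)
}

# full-detail hairpin oracle; returns the best score, and whether some fold
# pairs the complete tail exclusively on G/C
oracle_hairpin <- function(a, tail_length, min_loop = 3, wgc = 2, wat = 1,
                           cap = Inf) {
  n <- nchar(a)
  if (n < tail_length + min_loop + 1) return(0)
  chars <- strsplit(a, "")[[1]]
  tail_pos <- seq(n - tail_length + 1, n)
  tc <- chars[tail_pos]
  best <- 0
  for (const in 2:(2 * n)) {      # tail index i + upstream position j = const
    sc <- 0
    for (i in seq_len(tail_length)) {
      j <- const - i
      if (j >= 1 && j <= n && tail_pos[i] - j - 1 >= min_loop &&
          tc[i] != "N" && chars[j] == .ORACLE_COMP[[tc[i]]]) {
        sc <- sc + .oracle_pair_weight(tc[i], wgc, wat)
      }
    }
    if (sc > best) best <- sc
  }
  min(best, cap)
}

# TRUE iff some antiparallel offset pairs the complete tail of a against b
# with every pair G/C
oracle_perfect_gc_tail <- function(a, b, tail_length) {
  lt <- min(tail_length, nchar(a))
  tc <- strsplit(substring(a, nchar(a) - lt + 1, nchar(a)), "")[[1]]
  bc <- strsplit(b, "")[[1]]
  if (!all(tc %in% c("G", "C"))) return(FALSE)
  for (const in 2:(lt + length(bc))) {
    ok <- TRUE
    for (i in seq_len(lt)) {
      j <- const - i
      if (j < 1 || j > length(bc) || bc[j] != .ORACLE_COMP[[tc[i]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# ---- binding-site oracle ---------------------------------------------------
# Naive scan of every offset; a minus-strand site is a window whose reverse
# complement the primer matches. Ns never match.

oracle_hamming <- function(p_chars, w_chars) {
  sum(p_chars != w_chars | p_chars == "N" | w_chars == "N")
}

oracle_binding_sites <- function(primer, template, max_mismatches,
                                 three_prime_exact = 0,
                                 both_strands = TRUE) {
  pc <- strsplit(primer, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  m <- length(pc); n <- length(tc)
  tpe <- min(three_prime_exact, m)
  out <- NULL
  if (m <= n) {
    for (o in seq_len(n - m + 1)) {
      w <- tc[o:(o + m - 1)]
      mm <- oracle_hamming(pc, w)
      ok3 <- tpe == 0 ||
        oracle_hamming(pc[(m - tpe + 1):m], w[(m - tpe + 1):m]) == 0
      if (mm <= max_mismatches && ok3) {
        out <- rbind(out, data.frame(start = o, end = o + m - 1, strand = "+",
                                     mismatches = mm))
      }
      if (both_strands) {
        wrc <- rev(.ORACLE_COMP[w])
        mm2 <- oracle_hamming(pc, wrc)
        ok32 <- tpe == 0 ||
          oracle_hamming(pc[(m - tpe + 1):m], wrc[(m - tpe + 1):m]) == 0
        if (mm2 <= max_mismatches && ok32) {
          out <- rbind(out, data.frame(start = o, end = o + m - 1,
                                       strand = "-", mismatches = mm2))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

oracle_products <- function(fsites, rsites, max_len) {
  out <- NULL
  fs <- fsites[fsites$strand == "+", , drop = FALSE]
  rs <- rsites[rsites$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      len <- rs$end[j] - fs$start[i] + 1
      if (len > 0 && len <= max_len) {
        out <- rbind(out, data.frame(forward_start = fs$start[i],
                                     reverse_end = rs$end[j],
                                     product_length = len))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(forward_start = integer(), reverse_end = integer(),
                      product_length = integer())
  }
  out[order(out$forward_start, out$reverse_end), , drop = FALSE]
}

site_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$start, df$end, df$strand, df$mismatches, sep = ":"))
}
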