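# Independent audit of the microsatellite flanking-primer constraint set.
# Each constraint is re-checked from the raw sequences: GC by direct
# counting, Tm by the independent summation oracle, binding uniqueness by
# the naive scan oracle. Returns a character vector of violated constraints
# (empty = pass).

audit_flanking_pair <- function(read_bases, ms, pair,
                                cfg = ssr_design_config()) {
  bad <- character()
  fb <- pair$forward_bases; rvb <- pair$reverse_bases
  fl <- nchar(fb); rl <- nchar(rvb)
  # 1. primer lengths 20-30
  if (fl < cfg$primer_length_min || fl > cfg$primer_length_max ||
      rl < cfg$primer_length_min || rl > cfg$primer_length_max) {
    bad <- c(bad, "length")
  }
  # 2. product size bounds and repeat span
  rev_end <- pair$reverse_start + pair$reverse_length - 1
  prod_len <- rev_end - pair$forward_start + 1
  if (prod_len < cfg$product_min || prod_len > cfg$product_max ||
      prod_len != pair$product_length) {
    bad <- c(bad, "product_size")
  }
  if (!(pair$forward_start + fl - 1 < ms$start && pair$reverse_start > ms$end)) {
    bad <- c(bad, "span")
  }
  # 3. product free of Ns
  product <- substring(read_bases, pair$forward_start, rev_end)
  if (grepl("N", product, fixed = TRUE)) bad <- c(bad, "product_N")
  # 4. matched GC, Tm near preferred (independent computations)
  count_gc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch %in% c("G", "C")) / length(ch)
  }
  if (abs(count_gc(fb) - count_gc(rvb)) > cfg$gc_tolerance + 1e-12) {
    bad <- c(bad, "gc_match")
  }
  for (b in c(fb, rvb)) {
    if (abs(oracle_tm_nn(b, "santalucia_nn") - cfg$preferred_tm) >
        cfg$tm_tolerance + 1e-9) {
      bad <- c(bad, "tm")
      break
    }
  }
  # 5. no tandem copy of the repeat unit (either orientation) in a primer
  unit2 <- strrep(ms$unit, 2)
  unit2rc <- strrep(oracle_revcomp(ms$unit), 2)
  if (grepl(unit2, fb, fixed = TRUE) || grepl(unit2rc, fb, fixed = TRUE) ||
      grepl(unit2, rvb, fixed = TRUE) || grepl(unit2rc, rvb, fixed = TRUE)) {
    bad <- c(bad, "unit_in_primer")
  }
  # 6. primers and the flanks up to the repeat are microsatellite-free
  up_flank <- substring(read_bases, pair$forward_start + fl, ms$start - 1)
  down_flank <- substring(read_bases, ms$end + 1, pair$reverse_start - 1)
  for (s in c(fb, rvb, up_flank, down_flank)) {
    if (nchar(s) > 0 && nrow(find_microsatellites(s, cfg$relaxed)) > 0) {
      bad <- c(bad, "other_microsatellite")
      break
    }
  }
  # 7. exactly one within-read binding site per primer (naive oracle)
  for (b in c(fb, rvb)) {
    sites <- oracle_binding_sites(b, read_bases,
                                  max_mismatches = nchar(b) %/% 5,
                                  three_prime_exact = 5)
    if (nrow(sites) != 1) {
      bad <- c(bad, "non_specific_binding")
      break
    }
  }
  bad
}
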