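test_that("candidate enumeration matches the closed form and slices the template", {
  set.seed(131)
  tmpl <- random_oligo(400)
  spec <- generation_spec(101, 300, length_min = 18, length_max = 23,
                          forbid_n = FALSE)
  cands <- generate_candidates(tmpl, spec)
  expect_equal(nrow(cands), sum(200 - 18:23 + 1))   # 1083
  expect_equal(nrow(cands), 1083)
  expect_identical(cands$bases,
                   substring(tmpl, cands$start, cands$start + cands$length - 1))
  # deterministic order: start, then length
  expect_identical(order(cands$start, cands$length), seq_len(nrow(cands)))
})

test_that("closed-form count holds for other window/length combinations", {
  set.seed(141)
  tmpl <- random_oligo(600)
  for (i in 1:5) {
    ws <- sample(1:100, 1); we <- ws + sample(50:300, 1)
    lmin <- sample(15:20, 1); lmax <- lmin + sample(0:10, 1)
    spec <- generation_spec(ws, we, length_min = lmin, length_max = lmax,
                            forbid_n = FALSE)
    wl <- we - ws + 1
    want <- sum(pmax(0, wl - seq(lmin, min(lmax, wl)) + 1))
    expect_equal(nrow(generate_candidates(tmpl, spec)), want)
  }
})

test_that("window smaller than length_min gives an empty result with status", {
  out <- generate_candidates(strrep("A", 100),
                             generation_spec(10, 20, length_min = 18,
                                             length_max = 23))
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "status"), "smaller")
})

test_that("hard sequence filters are sound", {
  tmpl <- paste0("ATGATCCGTAAT", strrep("N", 30), "ATTATTAATTAAGGATTA")
  n <- nchar(tmpl)
  all_n <- generate_candidates(tmpl, generation_spec(13, 42, length_min = 10,
                                                     length_max = 12))
  expect_equal(nrow(all_n), 0)

  set.seed(151)
  tmpl2 <- random_oligo(300)
  no_c <- generate_candidates(tmpl2,
                              generation_spec(1, 300, length_min = 12,
                                              length_max = 18, forbid_c = TRUE))
  expect_false(any(grepl("C", no_c$bases, fixed = TRUE)))
  no_g <- generate_candidates(tmpl2,
                              generation_spec(1, 300, length_min = 12,
                                              length_max = 18, forbid_g = TRUE))
  expect_false(any(grepl("G", no_g$bases, fixed = TRUE)))
  no_motif <- generate_candidates(tmpl2,
                                  generation_spec(1, 300, length_min = 12,
                                                  length_max = 18,
                                                  excluded_motifs = c("ACGT", "TTT")))
  expect_false(any(grepl("ACGT", no_motif$bases, fixed = TRUE)))
  expect_false(any(grepl("TTT", no_motif$bases, fixed = TRUE)))
  bounded <- generate_candidates(tmpl2,
                                 generation_spec(1, 300, length_min = 12,
                                                 length_max = 18,
                                                 gc_min = 0.4, gc_max = 0.6))
  gc <- vapply(bounded$bases, gc_content, numeric(1))
  expect_true(all(gc >= 0.4 & gc <= 0.6))
})

test_that("reverse-orientation candidates are the reverse complement of their slice", {
  set.seed(161)
  tmpl <- random_oligo(120)
  cands <- generate_candidates(tmpl, generation_spec(20, 80, length_min = 15,
                                                     length_max = 16),
                               orientation = "reverse")
  slice <- substring(tmpl, cands$start, cands$start + cands$length - 1)
  expect_identical(cands$bases,
                   vapply(slice, reverse_complement, character(1),
                          USE.NAMES = FALSE))
})

test_that("evaluation fills characteristics, is idempotent, and sees the self-match", {
  set.seed(171)
  tmpl <- dna_sequence(random_oligo(300), id = "t")
  spec <- generation_spec(50, 120, length_min = 18, length_max = 20)
  cands <- generate_candidates(tmpl, spec)[1:10, ]
  ev <- evaluate_candidates(cands, tmpl)
  expect_true(all(is.finite(ev$gc)), all(is.finite(ev$tm)))
  expect_true(all(ev$binding_count >= 1))        # every candidate matches its own locus
  ev2 <- evaluate_candidates(ev, tmpl)
  expect_identical(ev, ev2)
  # all-A candidate has zero self-dimer score
  allA <- evaluate_candidates(data.frame(bases = strrep("A", 20), start = NA,
                                         length = 20, orientation = "forward"),
                              strrep("A", 100))
  expect_equal(allA$self_dimer, 0)
})

test_that("long candidates (18-110 bases) pass through every analysis path", {
  set.seed(181)
  tmpl <- dna_sequence(random_oligo(2000), id = "t")
  for (len in c(18, 40, 80, 110)) {
    start <- 200
    cand <- data.frame(bases = substring(tmpl$bases, start, start + len - 1),
                       start = start, length = len, orientation = "forward")
    ev <- evaluate_candidates(cand, tmpl)
    expect_true(is.finite(ev$tm) && is.finite(ev$hairpin) &&
                  is.finite(ev$self_dimer) && ev$binding_count >= 1,
                label = sprintf("length %d", len))
  }
})

test_that("pairing respects product bounds and fills pair characteristics", {
  set.seed(191)
  tmpl <- dna_sequence(random_oligo(400), id = "t")
  fwd <- evaluate_candidates(
    data.frame(bases = substring(tmpl$bases, 1, 20), start = 1, length = 20,
               orientation = "forward"), tmpl, count_binding = FALSE)
  rev <- evaluate_candidates(
    data.frame(bases = reverse_complement(substring(tmpl$bases, 131, 150)),
               start = 131, length = 20, orientation = "reverse"),
    tmpl, count_binding = FALSE)
  pairs <- make_pairs(fwd, rev, 80, 300)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$product_length, 150)
  expect_true(all(c("pair_dimer", "tm_difference", "gc_difference",
                    "length_difference") %in% names(pairs)))
  expect_equal(pairs$tm_difference, abs(fwd$tm - rev$tm))
  expect_equal(nrow(make_pairs(fwd, rev, 200, 300)), 0)
})

test_that("pairing is Cartesian within bounds", {
  set.seed(201)
  tmpl <- dna_sequence(random_oligo(1000), id = "t")
  fwd <- evaluate_candidates(
    data.frame(bases = substring(tmpl$bases, c(1, 11, 21), c(20, 30, 40)),
               start = c(1, 11, 21), length = 20, orientation = "forward"),
    tmpl, count_binding = FALSE)
  rev <- evaluate_candidates(
    data.frame(bases = vapply(c(301, 321, 341, 361), function(s)
      reverse_complement(substring(tmpl$bases, s, s + 19)), character(1)),
      start = c(301, 321, 341, 361), length = 20, orientation = "reverse"),
    tmpl, count_binding = FALSE)
  pairs <- make_pairs(fwd, rev, 1, 1000)
  expect_equal(nrow(pairs), 12)
})

test_that("chimeric primers concatenate and stay analysable", {
  set.seed(211)
  head40 <- random_oligo(40)
  tail40 <- random_oligo(40)
  cand <- chimeric_primer(head40, tail40)
  expect_equal(cand$length, 80)
  expect_identical(cand$bases, paste0(head40, tail40))
  ev <- evaluate_candidates(cand, paste0("TTTT", head40, tail40, "TTTT"))
  expect_true(is.finite(ev$hairpin) && is.finite(ev$self_dimer) &&
                is.finite(ev$tm) && ev$binding_count >= 1)
  expect_identical(chimeric_primer(head40)$bases, head40)
  expect_error(chimeric_primer(random_oligo(70), random_oligo(60)), "exceeds")
})
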