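test_that("planted exact, mismatched and minus-strand sites are found; decoys beyond the budget are not", {
  set.seed(81)
  primer <- random_oligo(20)
  fx <- make_template(1000, seed = 4711, plants = list(
    list(sequence = primer, position = 101),
    list(sequence = primer, position = 401, mismatches = 2, spacing = "even"),
    list(sequence = primer, position = 651, mismatches = 3, spacing = "even"),
    list(sequence = primer, position = 851, strand = "-")),
    verify = match_params(max_mismatches = 3, three_prime_exact = 0))
  p <- match_params(max_mismatches = 2, three_prime_exact = 0)
  sites <- find_binding_sites(primer, fx$sequence, p)
  expect_identical(site_key(sites),
                   site_key(data.frame(start = c(101, 401, 851),
                                       end = c(120, 420, 870),
                                       strand = c("+", "+", "-"),
                                       mismatches = c(0, 2, 0))))
  # the 3-mismatch decoy appears once the budget allows it
  sites3 <- find_binding_sites(primer, fx$sequence,
                               match_params(max_mismatches = 3,
                                            three_prime_exact = 0))
  expect_true(any(sites3$start == 651 & sites3$mismatches == 3))
})

test_that("binding-site sets equal the naive Hamming oracle and Biostrings on random templates", {
  set.seed(91)
  for (i in 1:12) {
    tmpl <- random_oligo(800)
    primer <- substring(tmpl, 301, 320)       # guarantees at least one site
    max_mm <- sample(0:3, 1)
    p <- match_params(max_mismatches = max_mm, three_prime_exact = 0)
    got <- find_binding_sites(primer, tmpl, p)
    want <- oracle_binding_sites(primer, tmpl, max_mm)
    expect_identical(site_key(got), site_key(want))
    # independent cross-check of plus-strand hits with Biostrings
    bs <- Biostrings::matchPattern(primer, Biostrings::DNAString(tmpl),
                                   max.mismatch = max_mm)
    expect_setequal(got$start[got$strand == "+"], BiocGenerics::start(bs))
  }
})

test_that("the 3'-exact block vetoes sites with 3'-end mismatches", {
  tmpl <- paste0(strrep("A", 50), "GGGGGTTTTTCCCCC", strrep("A", 50))
  primer <- "GGGGGTTTTTCCCCC"
  exact <- find_binding_sites(primer, tmpl, match_params(max_mismatches = 2,
                                                         three_prime_exact = 5))
  expect_equal(exact$start, 51)
  # mutate the template base under the primer's final base
  tmpl2 <- paste0(strrep("A", 50), "GGGGGTTTTTCCCCA", strrep("A", 50))
  hit <- find_binding_sites(primer, tmpl2, match_params(max_mismatches = 2,
                                                        three_prime_exact = 5))
  expect_false(any(hit$strand == "+" & hit$start == 51))
  # with a pure Hamming criterion the site is back
  hit0 <- find_binding_sites(primer, tmpl2, match_params(max_mismatches = 2,
                                                         three_prime_exact = 0))
  expect_true(any(hit0$strand == "+" & hit0$start == 51))
})

test_that("minus-strand 3' anchoring is at the low-coordinate side", {
  set.seed(101)
  tmpl <- random_oligo(300)
  primer <- reverse_complement(substring(tmpl, 101, 124))
  # mutating the template base at the site's low end hits the primer's 3' end
  ch <- strsplit(tmpl, "")[[1]]
  ch[101] <- setdiff(c("A", "C", "G", "T"), ch[101])[1]
  tmpl_mut <- paste(ch, collapse = "")
  p <- match_params(max_mismatches = 2, three_prime_exact = 3)
  expect_true(any(find_binding_sites(primer, tmpl, p)$start == 101))
  expect_false(any(find_binding_sites(primer, tmpl_mut, p)$start == 101))
})

test_that("counts, degenerate inputs and case/wrap invariance behave", {
  tmpl <- dna_sequence(paste0(strrep("T", 30), "ACGTACGTACGTACGTACGT",
                              strrep("T", 30), "ACGTACGTACGTACGTACGT",
                              strrep("T", 30)), id = "t")
  primer <- "ACGTACGTACGTACGTACGT"
  p <- match_params(max_mismatches = 0, three_prime_exact = 0)
  got <- find_binding_sites(primer, tmpl, p)
  # exact plants twice; the palindromic-ish primer may also hit minus strand
  expect_equal(count_binding_sites(primer, tmpl, p), nrow(got))
  expect_equal(sum(got$strand == "+" & got$mismatches == 0), 2)
  expect_identical(site_key(got), site_key(oracle_binding_sites(primer, tmpl$bases, 0)))
  # no-match template
  expect_equal(count_binding_sites("GGGGGGGG", strrep("A", 100), p), 0)
  # primer longer than template: empty with status
  long <- find_binding_sites(strrep("A", 30), "ACGT", p)
  expect_equal(nrow(long), 0)
  expect_match(attr(long, "status"), "longer")
  # lower-case input is normalised
  expect_equal(count_binding_sites(tolower(primer), tmpl, p), nrow(got))
})

test_that("Ns never count as matches", {
  tmpl <- paste0(strrep("A", 20), "GGGGGNGGGG", strrep("A", 20))
  expect_equal(count_binding_sites("GGGGGGGGGG", tmpl,
                                   match_params(max_mismatches = 0,
                                                three_prime_exact = 0,
                                                both_strands = FALSE)), 0)
  expect_equal(count_binding_sites("GGGGGGGGGG", tmpl,
                                   match_params(max_mismatches = 1,
                                                three_prime_exact = 0,
                                                both_strands = FALSE)), 1)
})

test_that("product search pairs convergent sites within the window", {
  set.seed(111)
  fwd <- random_oligo(20)
  rev <- random_oligo(20)
  fx <- make_template(1500, seed = 271, plants = list(
    list(sequence = fwd, position = 101),
    list(sequence = rev, position = 481, strand = "-")),
    verify = match_params(max_mismatches = 1, three_prime_exact = 0))
  p <- match_params(max_mismatches = 1, three_prime_exact = 0)
  prods <- search_for_pcr_products(fwd, rev, fx$sequence,
                                   max_product_length = 3500, p = p)
  expect_equal(nrow(prods), 1)
  expect_equal(prods$product_length, 400)
  expect_equal(prods$forward_start, 101)
  expect_equal(prods$reverse_end, 500)
  expect_false(attr(prods, "secondary_products"))
  # out-of-window pairing yields no product
  prods2 <- search_for_pcr_products(fwd, rev, fx$sequence,
                                    max_product_length = 300, p = p)
  expect_equal(nrow(prods2), 0)
})

test_that("multiple convergent pairs are all enumerated and flagged", {
  set.seed(121)
  fwd <- random_oligo(20)
  rev <- random_oligo(20)
  fx <- make_template(4000, seed = 1331, plants = list(
    list(sequence = fwd, position = 101),
    list(sequence = fwd, position = 1001),
    list(sequence = rev, position = 1481, strand = "-"),
    list(sequence = rev, position = 2281, strand = "-")),
    verify = match_params(max_mismatches = 1, three_prime_exact = 0))
  p <- match_params(max_mismatches = 1, three_prime_exact = 0)
  prods <- search_for_pcr_products(fwd, rev, fx$sequence,
                                   max_product_length = 3500, p = p)
  want <- oracle_products(oracle_binding_sites(fwd, fx$sequence$bases, 1),
                          oracle_binding_sites(rev, fx$sequence$bases, 1),
                          3500)
  expect_equal(nrow(prods), 4)
  expect_equal(prods$forward_start, want$forward_start)
  expect_equal(prods$reverse_end, want$reverse_end)
  expect_equal(prods$product_length, want$product_length)
  expect_true(attr(prods, "secondary_products"))
})
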