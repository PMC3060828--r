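cns <- design_constraints()

test_that("Tm and length penalties count out-of-window primers", {
  expect_equal(unname(tm_penalties(58.2, 57.3, cns)), c(0, 0))
  expect_equal(unname(tm_penalties(53.9, 57.0, cns)), c(1, 1))
  expect_equal(unname(tm_penalties(54.0, 65.0, cns)), c(0, 1))  # bounds inclusive

  expect_equal(unname(length_penalties(22, 22, cns)), c(0, 0))
  expect_equal(unname(length_penalties(25, 26, cns)), c(0, 0))
  expect_equal(unname(length_penalties(17, 29, cns)), c(2, 1))
})

test_that("GC and product-length penalties behave as graded terms", {
  expect_equal(gc_penalty(45.5, 40.9, cns), 0)
  expect_equal(gc_penalty(34.6, 50.0, cns), 1)
  expect_equal(gc_penalty(0, 100, cns), 2)

  expect_equal(product_length_penalty(887, cns), 0)
  expect_equal(product_length_penalty(1092, cns), 0)
  expect_gt(product_length_penalty(700, cns), 0)
  # gradient toward the window
  expect_lt(product_length_penalty(790, cns), product_length_penalty(700, cns))
})

test_that("dimer check matches constructed cases and is symmetric", {
  expect_equal(dimer_check("AAAAAA", "TTTTTT", cns), 1)
  expect_equal(dimer_check("ACGT", "ACGT", cns), 0)
  expect_equal(dimer_check("GGGGGGCC", "GGCCCCCC", cns), 1)
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
      expect_equal(dimer_check(a, b, cns), dimer_check(b, a, cns))
    }
  })
})

test_that("dimer pairing counts agree with per-offset oracle", {
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1), TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1), TRUE), collapse = "")
      for (mode in c("contiguous", "total")) {
        expect_equal(swarmprimer:::dimer_pairings(a, b, mode),
                     naive_dimer_pairings(a, b, mode),
                     info = paste(mode, a, b))
      }
    }
  })
})

test_that("hairpin check matches stem/loop enumeration", {
  expect_equal(hairpin_check("GGGGAAATTTCCCC", cns), 1)
  expect_equal(hairpin_check("ACACACACACACAC", cns), 0)
  expect_equal(hairpin_check("ACGTAC", cns), 0)  # too short for stem+loop+stem
  withr::with_seed(8, {
    for (i in 1:25) {
      p <- paste(sample(c("A", "C", "G", "T"), sample(12:30, 1), TRUE), collapse = "")
      expect_equal(hairpin_check(p, cns), naive_hairpin(p), info = p)
    }
  })
})

test_that("specificity counts extra binding sites on both strands", {
  tpl <- template_sequence(paste(rep("ACGTTGCAAC", 12), collapse = ""))
  p <- substr(tpl$seq, 11, 30)  # 20-mer repeated by construction
  expect_gt(specificity_check(p, tpl), 0)

  # unique site on a random template
  withr::with_seed(21, {
    rnd <- template_sequence(paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                   collapse = ""))
    q <- substr(rnd$seq, 101, 122)
    expect_equal(specificity_check(q, rnd),
                 naive_specificity(q, rnd$seq))
  })

  # circular rotations: ACGT occurs 4x plus-strand on circular ACGTACGT
  circ <- template_sequence("ACGTACGT", circular = TRUE)
  expect_equal(specificity_check("ACGT", circ),
               naive_specificity("ACGT", circ$seq))
  expect_gt(specificity_check("ACGT", circ), 0)

  # palindromic primer: plus- and minus-strand hits both count
  pal <- template_sequence(paste0("AAAAAAAAAA", "GAATTC", "TTTTTTTTTT"),
                           circular = FALSE)
  expect_equal(specificity_check("GAATTC", pal), 1)
  expect_error(specificity_check("ACGTACGTACGT", template_sequence("ACGT")),
               class = "swarmprimer_input_error")
})

test_that("terminal checks follow the 3'/5' composition rules", {
  expect_equal(gc_clamp_check("ATTTAGCCAATGACACCTAGCC"), 0)
  expect_equal(gc_clamp_check("AAGACGCTAGGTTGTGATTCTAG"), 0)
  expect_equal(gc_clamp_check("ACGTA"), 1)

  expect_equal(endmatch_check("AAAAGCC", "AAAAGGC", cns), 1)
  expect_equal(endmatch_check("AAAAAAA", "CCCAAA", cns), 0)
  expect_equal(endmatch_check("AAAACG", "AACGT", cns), 1)

  expect_equal(terminus_gc_check("ACTTGAGTTTCCCCCCTACCC", cns), 0)
  expect_equal(terminus_gc_check("GCGCGAAAAAAAAAAAAT", cns), 1)
  expect_equal(terminus_gc_check("GGGGGAAAAAAACCCCC", cns), 2)
  expect_error(terminus_gc_check("ACG", cns), class = "swarmprimer_input_error")
})

test_that("fitness is the weighted re-summation of its breakdown", {
  withr::with_seed(31, {
    fam <- make_conserved_family(2000, seed = 17)
    tpl <- fam$templates[[1]]
    reg <- conserved_regions(fam$alignment, "sim_01")
    w <- constraint_weights()
    for (i in 1:10) {
      pair <- list(fwd_start = sample(1800, 1), fwd_len = sample(18:28, 1),
                   rev_len = sample(18:28, 1), product_len = sample(700:1200, 1))
      bd <- evaluate_primer_pair(pair, tpl, cns, w, regions = reg)
      terms <- unlist(bd[paste0("pen_", names(w))])
      expect_gte(min(terms), 0)
      expect_equal(bd$fitness, sum(unclass(w) * terms))
    }
  })
})

test_that("fitness scales linearly in the weight of a violated term", {
  tpl <- template_sequence(paste(rep("ACGTTGCAAC", 30), collapse = ""))
  pair <- list(fwd_start = 1, fwd_len = 20, rev_len = 20, product_len = 700)
  c2 <- design_constraints(product_min = 800, product_max = 1100)
  for (wpl in c(1, 5)) {
    w <- constraint_weights(product_len = wpl)
    bd <- evaluate_primer_pair(pair, tpl, c2, w)
    base <- evaluate_primer_pair(pair, tpl, c2, constraint_weights(product_len = 0))
    expect_equal(bd$fitness - base$fitness, wpl * bd$pen_product_len)
  }
  expect_gt(evaluate_primer_pair(pair, tpl, c2,
                                 constraint_weights())$pen_product_len, 0)
})
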