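# Sequence primitives and per-oligo physical properties.

published <- published_assays()

test_that("GC content matches the printed values for all published oligos", {
  expected <- list(
    humpback = c(forward = 55, probe = 63.6, reverse = 52.4),
    rockfish = c(forward = 60, probe = 53.8, reverse = 60),
    murre = c(forward = 55, probe = 62.5, reverse = 55))
  for (assay in names(expected)) {
    for (role in names(expected[[assay]])) {
      expect_equal(gc_content(published[[assay]][[role]]),
                   unname(expected[[assay]][role]),
                   info = paste(assay, role))
    }
  }
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGC"), 100)
})

test_that("GC content rejects ambiguity codes unless permissive", {
  expect_error(gc_content("ACGN"), "ambiguity")
  rng <- gc_content("ACGN", mode = "permissive")  # C,G certain; N could be
  expect_equal(unname(rng), c(50, 75))
  expect_error(gc_content(""), "non-empty")
})

test_that("nearest-neighbor Tm reproduces an independent reference", {
  # frozen values from a published NN implementation run at identical
  # parameters (SantaLucia-1998 table, entropic salt correction, CT/4)
  frozen <- c(
    GCCGCTCCATTAGATCACGA = 59.96787,
    TCGCACCGGGCCCATCAATCGT = 69.037885,
    TGGCCCTGAAGTAAGAACCAG = 59.648983,
    CAGGAGCATCAGTCGACCTG = 60.179116,
    ACACCCTTATTTGTGTGGGCCGTCCT = 68.193741,
    GAGAAGGAGAAGGACAGCGG = 59.825383,
    TGGCGCATGAGCTGGTATAG = 59.96608,
    ACCGCCCTAAGCCTGCTCATCCGT = 69.969482,
    TATTACAAAGGCGTGGGCGG = 60.745128)
  for (s in names(frozen)) {
    expect_equal(melting_temperature(s), unname(frozen[s]),
                 tolerance = 1e-5, info = s)
  }
  # variant conditions, same reference
  expect_equal(
    melting_temperature("GCCGCTCCATTAGATCACGA",
                        thermo_params(divalent_mM = 0, dntp_mM = 0)),
    54.229017, tolerance = 1e-5)
  expect_equal(
    melting_temperature("GCCGCTCCATTAGATCACGA",
                        thermo_params(monovalent_mM = 100, divalent_mM = 0,
                                      dntp_mM = 0)),
    57.55629, tolerance = 1e-5)
  expect_equal(
    melting_temperature("GCCGCTCCATTAGATCACGA",
                        thermo_params(divalent_mM = 3, dntp_mM = 0.8)),
    61.601381, tolerance = 1e-5)
  expect_equal(
    melting_temperature("GCCGCTCCATTAGATCACGA",
                        thermo_params(divalent_mM = 0, dntp_mM = 0,
                                      oligo_nM = 200)),
    56.111859, tolerance = 1e-5)
  expect_equal(melting_temperature("ATATATAT",
                                   thermo_params(divalent_mM = 0, dntp_mM = 0)),
               -20.356456, tolerance = 1e-4)
})

test_that("default Tm conditions track the printed oligo Tm column", {
  printed <- list(
    humpback = c(forward = 60, probe = 69, reverse = 59.6),
    rockfish = c(forward = 60.2, probe = 68.2, reverse = 59.8),
    murre = c(forward = 60, probe = 70, reverse = 60.7))
  for (assay in names(printed)) {
    for (role in names(printed[[assay]])) {
      expect_lt(abs(melting_temperature(published[[assay]][[role]]) -
                      printed[[assay]][role]), 1.5)
    }
  }
})

test_that("Tm obeys duplex symmetry, stacking order, and salt direction", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_dna(sample(12:30, 1))
      expect_equal(melting_temperature(s),
                   melting_temperature(reverse_complement(s)),
                   tolerance = 1e-10)
    }
  })
  expect_gt(melting_temperature(strrep("GC", 10)),
            melting_temperature(strrep("AT", 10)))
  lo <- melting_temperature("GCCGCTCCATTAGATCACGA",
                            thermo_params(monovalent_mM = 25))
  hi <- melting_temperature("GCCGCTCCATTAGATCACGA",
                            thermo_params(monovalent_mM = 150))
  expect_gt(hi, lo)
  expect_error(melting_temperature("ACGTACG"), "length >= 8")
  expect_error(melting_temperature("ACGTACGN"), "ambiguity")
})

test_that("reverse complement is the IUPAC-aware involution", {
  expect_equal(reverse_complement("GATC"), "GATC")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("RYSWKM"), "KMWSRY")
  withr::with_seed(7, {
    for (i in 1:50) {
      s <- random_dna(sample(1:60, 1))
      expect_equal(reverse_complement(reverse_complement(s)), s)
      expect_equal(gc_content(s), gc_content(reverse_complement(s)))
    }
  })
  expect_error(reverse_complement("ACG$T"), "position 4")
})

test_that("homopolymer runs are measured exactly", {
  expect_equal(max_homopolymer_run("ACACCCTTATTTGTGTGGGCCGTCCT"), 3)
  expect_equal(max_homopolymer_run("AAAAG"), 4)
  expect_equal(max_homopolymer_run("ACGT"), 1)
  withr::with_seed(3, {
    for (i in 1:50) {
      s <- random_dna(sample(1:40, 1))
      r <- max_homopolymer_run(s)
      expect_gte(r, 1)
      expect_lte(r, nchar(s))
      expect_equal(r == nchar(s), length(unique(chars(s))) == 1)
    }
  })
})

test_that("3'-end reports agree with an exhaustive character scan", {
  rep437 <- three_prime_report("TGGCCCTGAAGTAAGAACCAG")
  expect_equal(rep437$terminal_base, "G")
  expect_true(rep437$terminal_is_cg)
  expect_false(rep437$terminal_is_t)
  expect_equal(rep437$cg_in_last5, 3)

  rep287 <- three_prime_report("GCCGCTCCATTAGATCACGA")
  expect_equal(rep287$terminal_base, "A")
  expect_false(rep287$terminal_is_cg)
  expect_equal(rep287$cg_in_last5, 3)

  expect_equal(three_prime_report("GGGGG")$cg_in_last5, 5)
  expect_error(three_prime_report("ACGT"), "length >= 5")

  withr::with_seed(21, {
    for (i in 1:1000) {
      s <- random_dna(sample(5:30, 1))
      got <- three_prime_report(s)
      ch <- chars(s)
      tail5 <- ch[(length(ch) - 4):length(ch)]
      expect_equal(got$terminal_base, ch[length(ch)])
      expect_equal(got$cg_in_last5, sum(tail5 %in% c("C", "G")))
      expect_equal(got$terminal_is_t, ch[length(ch)] == "T")
    }
  })
})

test_that("oligo construction validates names, roles, and alphabet", {
  o <- oligo("287F", "gccgctccattagatcacga", "forward")
  expect_equal(o$sequence, "GCCGCTCCATTAGATCACGA")
  expect_equal(oligo_coordinate(o), 287L)
  expect_error(oligo("287F", "GCCGCT", "reverse"), "suffix")
  expect_error(oligo("X1", "ACGTN", "forward"), "invalid character|ambiguity")
  expect_warning(oligo("U1", "ACGU", "forward"), "mapped to T")
  expect_true(is.na(oligo_coordinate("probe")))
})
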