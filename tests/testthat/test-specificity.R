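# Mismatch-tolerant binding-site search and amplification prediction.

test_that("planted oligos are found at their planted positions", {
  withr::with_seed(101, {
    olig <- oligo("X1", random_dna(20), "forward")
    subject <- paste0(random_dna(40), olig$sequence, random_dna(40))
  })
  hits <- find_binding_sites(olig, subject, max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 41L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  expect_true(hits$three_prime_match)

  withr::with_seed(102, {
    subject2 <- paste0(random_dna(25), rc_naive(olig$sequence), random_dna(25))
  })
  hits2 <- find_binding_sites(olig, subject2, max_mismatches = 0)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 26L)
  # oligo longer than subject: empty, not an error
  expect_equal(nrow(find_binding_sites(olig, "ACGTACGT", 5)), 0)
})

test_that("binding-site search equals a brute-force Hamming scan", {
  withr::with_seed(103, {
    for (rep in 1:60) {
      olig <- random_dna(12)
      subject <- random_dna(70)
      got <- find_binding_sites(oligo("q1", olig, "forward"), subject, 3)
      want <- oracle_find_sites(olig, subject, 3)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$mismatches, want$mismatches)
      }
    }
  })
})

test_that("subject IUPAC codes match when they cover the oligo base", {
  o <- oligo("q1", "ATCGGACTGTCA", "forward")
  plant <- function(code) paste0("TTTT", "ATCG", code, "ACTGTCA", "TTTT")
  hits <- find_binding_sites(o, plant("N"), 0)     # N covers G
  expect_equal(hits$start, 5L)
  expect_equal(hits$strand, "+")
  expect_equal(find_binding_sites(o, plant("R"), 0)$start, 5L)  # R = A/G
  expect_equal(nrow(find_binding_sites(o, plant("Y"), 0)), 0)   # Y = C/T
  expect_error(find_binding_sites(oligo("q2", "ACGTN", "forward",
                                        allow_ambiguity = TRUE),
                                  "ACGTACGT", 0), "ambiguity")
})

test_that("site lists reflect under subject reverse-complementation", {
  withr::with_seed(107, {
    olig <- oligo("q1", random_dna(15), "forward")
    subject <- paste0(random_dna(30), olig$sequence, random_dna(30))
  })
  L <- nchar(subject)
  m <- 15
  fwd <- find_binding_sites(olig, subject, 2)
  rev <- find_binding_sites(olig, reverse_complement(subject), 2)
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(df) sort(paste(df$mismatches,
                                 ifelse(df$strand == "+", "-", "+"),
                                 L - (df$start + m - 1) + 1))
  expect_equal(sort(paste(fwd$mismatches, fwd$strand, fwd$start)), key(rev))
})

test_that("mismatch budgets are monotone in prediction outcome", {
  assay <- published_assays()$humpback
  cfg <- list(
    list(mm_f = 0, mm_p = 0, mm_r = 0),
    list(mm_f = 1, mm_p = 1, mm_r = 0),
    list(mm_f = 3, mm_p = 2, mm_r = 4),
    list(mm_f = 6, mm_p = 0, mm_r = 0),
    list(has_p = FALSE))
  panel <- generate_panel(assay, panel_spec(n = 5, seed = 77, configs = cfg))
  pos <- function(budget) vapply(panel$sequences, function(s)
    predict_amplification(assay, s,
                          screening_policy(max_mismatches = budget))$positive,
    logical(1))
  p1 <- pos(1); p4 <- pos(4); p6 <- pos(6)
  expect_true(all(p1 <= p4))
  expect_true(all(p4 <= p6))
  expect_equal(unname(p1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(p4), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(p6), c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("constructed subjects amplify (or fail) for the stated reason", {
  assay <- published_assays()$murre
  f <- assay$forward$sequence; r <- assay$reverse$sequence
  p <- assay$probe$sequence
  withr::with_seed(113, {
    sp1 <- random_dna(14); sp2 <- random_dna(50 - 14 - nchar(p))
  })
  core <- paste0(f, sp1, p, sp2, rc_naive(r))
  subj <- paste0("ACGTACGTAC", core, "GTACGTACGT")
  pred <- predict_amplification(assay, subj,
                                screening_policy(product_range = c(80, 200)))
  expect_true(pred$positive)
  expect_equal(pred$product_length, nchar(f) + 50 + nchar(r))
  expect_equal(pred$reason, "")

  # 6 substitutions in the F footprint exceed a budget of 5
  ch <- chars(subj)
  fpos <- 11:(10 + nchar(f))
  withr::with_seed(114, hitpos <- sample(fpos, 6))
  for (i in hitpos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  broken <- paste(ch, collapse = "")
  pred2 <- predict_amplification(assay, broken,
                                 screening_policy(max_mismatches = c(
                                   forward = 5, reverse = 5, probe = 5),
                                   product_range = c(80, 200)))
  expect_false(pred2$positive)
  expect_equal(pred2$reason, "no F")

  # product outside the allowed window
  pred3 <- predict_amplification(assay, subj,
                                 screening_policy(product_range = c(100, 200)))
  expect_false(pred3$positive)
  expect_equal(pred3$reason, "product out of range")

  # probe absent between the primers
  noprobe <- paste0("ACGTACGTAC", f, strrep("AT", 30), rc_naive(r),
                    "GTACGTACGT")
  pred4 <- predict_amplification(assay, noprobe,
                                 screening_policy(product_range = c(80, 200)))
  expect_false(pred4$positive)
  expect_equal(pred4$reason, "no P")
})

test_that("zero budgets reduce screening to exact substring search", {
  assay <- published_assays()$rockfish
  f <- assay$forward$sequence; r <- assay$reverse$sequence
  p <- assay$probe$sequence
  policy0 <- screening_policy(max_mismatches = 0, product_range = c(1, 1000))
  withr::with_seed(127, {
    for (rep in 1:50) {
      subj <- if (rep %% 2 == 0) {
        paste0(random_dna(10), f, random_dna(10), p, random_dna(10),
               rc_naive(r), random_dna(10))
      } else {
        random_dna(150)
      }
      got <- predict_amplification(assay, subj, policy0)$positive
      f_at <- gregexpr(f, subj, fixed = TRUE)[[1]]
      r_at <- gregexpr(rc_naive(r), subj, fixed = TRUE)[[1]]
      p_at <- c(gregexpr(p, subj, fixed = TRUE)[[1]],
                gregexpr(rc_naive(p), subj, fixed = TRUE)[[1]])
      want <- FALSE
      for (fs in f_at[f_at > 0]) for (rs in r_at[r_at > 0]) {
        re <- rs + nchar(r) - 1
        if (fs >= re) next
        for (ps in p_at[p_at > 0]) {
          if (ps > fs + nchar(f) - 1 && ps + nchar(p) - 1 < rs) want <- TRUE
        }
      }
      expect_equal(got, want, info = paste("panel", rep))
    }
  })
})

test_that("mismatch summaries average the per-sequence best sites", {
  assay <- published_assays()$humpback
  f <- assay$forward$sequence
  target <- paste0("ACGT", f, strrep("AC", 15), assay$probe$sequence,
                   strrep("GT", 15), rc_naive(assay$reverse$sequence), "ACGT")
  same <- stats::setNames(rep(target, 3), paste0("t", 1:3))
  summ <- mismatch_summary(assay, same)
  expect_equal(summ$mean_mm_forward, 0)
  expect_equal(summ$mean_mm_reverse, 0)
  expect_equal(summ$mean_mm_probe, 0)

  # planted 1, 2, 3 forward-primer mismatches average to 2
  withr::with_seed(131, {
    variants <- vapply(1:3, function(k) {
      ch <- chars(target)
      pos <- sample(5:(4 + nchar(f)), k)
      for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
      paste(ch, collapse = "")
    }, character(1))
  })
  names(variants) <- paste0("v", 1:3)
  summ2 <- mismatch_summary(assay, variants,
                            groups = stats::setNames(rep("grp", 3),
                                                     names(variants)))
  expect_equal(summ2$mean_mm_forward, 2)
  expect_equal(summ2$no_hit_forward, 0)

  # a sequence with no site within the cap is counted as a no-hit
  withr::with_seed(137, none <- c(x = random_dna(120)))
  summ3 <- mismatch_summary(assay, none, cap = 2)
  expect_equal(summ3$no_hit_forward, 1)
  expect_true(is.na(summ3$mean_mm_forward))
})
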