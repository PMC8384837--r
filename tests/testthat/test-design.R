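test_that("antiparallel register maps positions to repeats", {
  expect_equal(cognate_repeat(8), 1L)
  expect_equal(cognate_repeat(1), 8L)
  expect_equal(cognate_repeat(5), 4L)
  expect_equal(cognate_repeat(1:8), 8:1)
  expect_error(cognate_repeat(0), "1\\.\\.8")
  expect_error(cognate_repeat(9), "1\\.\\.8")
})

test_that("hamming distance counts differing positions", {
  expect_equal(hamming("UGUAAAUA", "UGUACGUA"), 2)
  expect_equal(hamming("UGUAAAUA", "UGUAAAUA"), 0)
  expect_equal(hamming("UGUAAAUA", "UAGACGAA"), 5)
  expect_error(hamming("UGUA", "UGUAAAUA"), "length")
  # brute-force position-wise oracle on random pairs
  set.seed(4)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "U"), 8, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 8, TRUE), collapse = "")
    ora <- sum(vapply(1:8, function(p)
      substr(a, p, p) != substr(b, p, p), logical(1)))
    expect_equal(hamming(a, b), ora)
  }
})

test_that("selection panel sizes match the screen layout", {
  mods <- rna_modules()
  expect_length(mods, 25)               # wild type + 24 single substitutions
  expect_equal(anyDuplicated(mods), 0)
  expect_equal(mods[1], wildtype_site())
  expect_true(all(vapply(mods[-1], function(m)
    hamming(m, wildtype_site()) == 1, logical(1))))
  cond <- screen_conditions()
  expect_equal(nrow(cond), 32)          # 8 repeats x 4 bases
  expect_equal(anyDuplicated(cond[, c("repeat_id", "base")]), 0)
  # each condition varies exactly the cognate position
  expect_equal(cond$position, 9L - cond$repeat_id)
  expect_true(all(vapply(seq_len(nrow(cond)), function(i)
    substr(cond$rna[i], cond$position[i], cond$position[i]) ==
      cond$base[i], logical(1))))
})

test_that("designs substitute code-table TRMs at cognate repeats", {
  d <- design_puf("UGUACGUA")
  expect_equal(d$substitutions, c(`4` = "TFR", `3` = "THE"))
  expect_equal(d$n_substitutions, 2)
  expect_length(d$gaps, 0)
  d2 <- design_puf("UUUAAAAC")
  expect_equal(d2$substitutions[c("1", "2", "7")],
               c(`1` = "QFR", `2` = "VFQ", `7` = "NPG"))
  expect_equal(d2$n_substitutions, 3)
  # wild-type target: no substitutions
  d3 <- design_puf(wildtype_site())
  expect_equal(d3$n_substitutions, 0)
  expect_equal(unname(d3$trms), unname(wildtype_trms()))
  # uncovered cells produce gaps, non-fatally
  d4 <- design_puf("UGGAAAUA")   # position 3 G -> repeat 6... covered;
  d5 <- design_puf("UGUAAAGA")   # position 7 G -> repeat 2, cell "---"
  expect_equal(d5$gaps, 7)
  expect_equal(d5$n_substitutions, 0)
  expect_equal(d4$substitutions, c(`6` = "SWD"))
  # substitution count + gaps = hamming distance to the site
  for (t in default_targets()) {
    d <- design_puf(t)
    expect_equal(d$n_substitutions + length(d$gaps),
                 hamming(t, wildtype_site()))
  }
  expect_error(design_puf("UGUA"), "8-mer")
  expect_error(design_puf("UGUAAATA"), "8-mer")
})

test_that("array generation emits the fixed and programmed blocks", {
  arr <- generate_array(seed = 7)
  expect_equal(nrow(arr), 1900)
  expect_equal(sum(arr$category != "programmed_random"), 900)
  expect_equal(sum(arr$category == "wildtype"), 20)
  tab <- table(arr$category[startsWith(arr$category, "target_")])
  expect_length(tab, 16)
  expect_true(all(tab == 55))
  # deterministic per seed; different across seeds
  expect_identical(generate_array(seed = 7), arr)
  expect_false(identical(generate_array(seed = 8)$seq, arr$seq))
  # RNA alphabet only
  expect_false(any(grepl("[^ACGU]", arr$seq)))
  # default target panel matches the published distance spectrum
  dist <- sort(vapply(default_targets(), hamming, numeric(1),
                      b = wildtype_site()))
  expect_equal(unname(dist), c(1, 2, 2, rep(3, 8), 4, 4, 4, 5, 6))
  expect_error(generate_array(targets = default_targets()[1:3]),
               "16 target")
  bad_probs <- array_position_probs(); bad_probs[1, 1] <- 0.5
  expect_error(generate_array(probs = bad_probs), "sum to 1")
})

test_that("programmed random block converges to the position vectors", {
  arr <- generate_array(n_random = 1e5, seed = 3)
  rand <- arr$seq[arr$category == "programmed_random"]
  p <- array_position_probs()
  # position 1: U at 0.70 within ~3 binomial SE
  fr_u1 <- mean(substr(rand, 1, 1) == "U")
  expect_lt(abs(fr_u1 - 0.70), 3 * sqrt(0.7 * 0.3 / 1e5))
  # chi-square GOF across all positions at the printed vectors
  for (pos in 1:8) {
    obs <- table(factor(substr(rand, pos, pos), levels = c("A", "U", "G",
                                                           "C")))
    expect_gt(suppressWarnings(
      chisq.test(obs, p = p[pos, c("A", "T", "G", "C")])$p.value), 1e-4)
  }
})

test_that("register-shift candidate sets have the published structure", {
  t <- "UGUAAAUA"
  s1 <- shift_candidates(t, 1)
  expect_length(s1, 3)
  expect_setequal(s1, c("UGUAAAUC", "UGUAAAUG", "UGUAAAUU"))
  s2 <- shift_candidates(t, 2)
  expect_length(s2, 9)
  expect_error(shift_candidates(t, 3), "1 or 2")
  # brute-force oracle: enumerate all 8-mers matching the definitions
  all_bases <- c("A", "C", "G", "U")
  enum <- expand.grid(rep(list(all_bases), 2), stringsAsFactors = FALSE)
  ora2 <- apply(enum, 1, function(bb) {
    v <- strsplit(t, "")[[1]]; v[7:8] <- bb
    paste(v, collapse = "")
  })
  ora2 <- ora2[vapply(ora2, function(x)
    substr(x, 7, 7) != substr(t, 7, 7) &&
      substr(x, 8, 8) != substr(t, 8, 8), logical(1))]
  expect_setequal(s2, ora2)
  # mirrored 5' definitions
  expect_length(shift_candidates(t, 1, "5p"), 3)
  f2 <- shift_candidates(t, 2, "5p")
  expect_length(f2, 9)
  expect_true(all(substr(f2, 3, 8) == substr(t, 3, 8)))
  # disjoint from the target, for random targets
  set.seed(8)
  for (i in 1:10) {
    tt <- paste(sample(all_bases, 8, TRUE), collapse = "")
    expect_false(tt %in% shift_candidates(tt, 1))
    expect_false(tt %in% shift_candidates(tt, 2))
    expect_length(shift_candidates(tt, 2), 9)
  }
})

test_that("selection ranking excludes artifacts and reports ranks", {
  sc <- data.frame(seq = c("UGUACGUA", "UGUAAAUA", "UCCGACUA", "AAAAAAAA"),
                   rep1 = c(6, 3, 9, 1), rep2 = c(5.5, 2.5, 8, 0.5),
                   stringsAsFactors = FALSE)
  r <- evaluate_selection(sc, target = "UGUACGUA")
  expect_equal(r$target_rank, 1)
  expect_equal(r$wildtype_rank, 2)
  expect_false("UCCGACUA" %in% r$ranking$seq)   # artifact removed
  expect_equal(r$excluded, "UCCGACUA")
  expect_false(r$discordant)
  # opposite replicate orders: mean-based rank with discordance flag
  sc2 <- data.frame(seq = c("A", "B", "C"), rep1 = c(3, 2, 1),
                    rep2 = c(1, 2, 3))
  r2 <- evaluate_selection(sc2, target = "A", wildtype = "C",
                           exclude = character(0))
  expect_true(r2$discordant)
  expect_equal(nrow(r2$ranking), 3)
  expect_error(evaluate_selection(
    data.frame(seq = "UCCGACUA", rep1 = 1), target = "X"), "remain")
})

test_that("closed loop: designs rank their intended target first", {
  # ground-truth activity of an RNA decreases with Hamming distance to
  # the design's intended site; selection + ranking must recover the
  # intended target at rank 1 for every covered design
  arr <- generate_array(seed = 21)
  seqs <- unique(arr$seq)
  freq <- as.numeric(table(arr$seq)[seqs])
  freq <- freq / sum(freq)
  covered <- Filter(function(t) length(design_puf(t)$gaps) == 0,
                    default_targets())
  expect_gt(length(covered), 3)
  for (t in covered) {
    act <- 8 - vapply(seqs, hamming, numeric(1), b = t)
    reps <- lapply(c(101, 202), function(s) {
      p <- simulate_library_pools(act, freq, depth = 1e5, seed = s)
      log2(((p$selected + (p$selected == 0)) / sum(p$selected)) /
             (p$input / sum(p$input)))
    })
    sc <- data.frame(seq = seqs, rep1 = reps[[1]], rep2 = reps[[2]])
    sc <- sc[is.finite(sc$rep1) & is.finite(sc$rep2), ]
    r <- evaluate_selection(sc, target = t)
    expect_equal(r$target_rank, 1)
  }
})
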