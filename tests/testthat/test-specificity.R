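test_that("hit selection applies strict thresholds and excludes nonsense", {
  st <- make_score_table(rbind(
    c(1.0, 0.5, -1, 6.2),    # hit: max 6.2 > 5, gap 5.2 > 4, prefers U
    c(0, 0, 0, 4.9),         # max not > 5
    c(5, 0, 0, 8),           # gap 3, not a hit
    c(0, 0, 0, 7)), trms = c("NWS", "NFS", "TFR", "QFR"))
  h <- select_hits(st)
  expect_equal(nrow(h), 2)
  expect_setequal(paste0(h$aa12, h$aa13, h$aa16), c("NWS", "QFR"))
  expect_equal(unique(h$preferred_base), "U")
  expect_equal(h$specificity[h$aa12 == "N"], 5.2)
  # nonsense exclusion
  stn <- make_score_table(rbind(c(0, 0, 0, 9)), trms = "N*S",
                          is_nonsense = TRUE)
  expect_equal(nrow(select_hits(stn)), 0)
  # monotonicity: raising either threshold never adds members
  set.seed(2)
  big <- make_score_table(matrix(rnorm(400, 3, 3), ncol = 4))
  for (s_min in c(4, 5, 6)) for (d_min in c(3, 4, 5)) {
    h1 <- select_hits(big, s_min, d_min)
    h2 <- select_hits(big, s_min + 1, d_min)
    h3 <- select_hits(big, s_min, d_min + 1)
    k <- function(h) paste0(h$aa12, h$aa13, h$aa16)
    expect_true(all(k(h2) %in% k(h1)))
    expect_true(all(k(h3) %in% k(h1)))
  }
})

test_that("clustering groups hits by preferred base", {
  st <- make_score_table(rbind(
    c(0.2, 0.1, 0.0, 6.0), c(0.1, 0.3, 0.2, 6.3),   # U-specific
    c(0.0, 6.1, 0.1, 0.2), c(0.2, 6.4, 0.0, 0.1)))  # C-specific
  h <- select_hits(st)
  cl <- cluster_hits(h)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[cl$preferred_base == "U"])), 1)
  expect_equal(length(unique(cl$cluster[cl$preferred_base == "C"])), 1)
  # identical rows fall in a single cluster
  st2 <- make_score_table(matrix(rep(c(0, 0, 0, 6), each = 3), ncol = 4))
  expect_equal(unique(cluster_hits(select_hits(st2))$cluster), 1L)
  # row-permutation invariance after canonical sorting
  perm <- h[c(3, 1, 4, 2), ]
  class(perm) <- class(h)
  cl2 <- cluster_hits(perm)
  expect_equal(cl$cluster, cl2$cluster)
  expect_error(cluster_hits(h[1, ]), "at least 2")
})

test_that("planted four-base classes are recovered by clustering", {
  # 100 rows with known base classes, sd 0.1 noise around the archetypes
  set.seed(31)
  base_of <- sample(1:4, 100, replace = TRUE)
  arch <- diag(4) * 6
  m <- arch[base_of, ] + matrix(rnorm(400, 0, 0.1), ncol = 4)
  st <- make_score_table(m)
  cl <- cluster_hits(select_hits(st))
  truth_lab <- base_of[match(paste0(cl$aa12, cl$aa13, cl$aa16),
                             paste0(st$aa12, st$aa13, st$aa16))]
  ari <- mclust::adjustedRandIndex(cl$cluster, truth_lab)
  expect_gt(ari, 0.9)
})

test_that("large clusters subgroup by residue property signature", {
  members <- data.frame(
    aa12 = c(rep("T", 6), rep("N", 6)),
    aa13 = "F",
    aa16 = c(rep("R", 6), rep("S", 6)), stringsAsFactors = FALSE)
  sg <- subgroup_by_property(members)
  expect_equal(length(unique(sg$subgroup)), 2)  # R+ at 16 vs S at 16
  expect_equal(length(unique(sg$subgroup[sg$aa16 == "R"])), 1)
  # at or below the size threshold: one group
  sg2 <- subgroup_by_property(members[1:10, ])
  expect_equal(unique(sg2$subgroup), 1L)
  # identical TRMs: one subgroup regardless of size
  same <- data.frame(aa12 = rep("Q", 12), aa13 = "F", aa16 = "R")
  expect_equal(unique(subgroup_by_property(same)$subgroup), 1L)
})

test_that("logos have unit column sums and bounded information", {
  lg <- build_logo(data.frame(aa12 = c("N", "N"), aa13 = c("Y", "H"),
                              aa16 = c("Q", "Q")))
  expect_equal(colSums(lg$freq), c(pos12 = 1, pos13 = 1, pos16 = 1))
  expect_equal(lg$freq["N", "pos12"], 1)
  expect_equal(unname(lg$information[c("pos12", "pos16")]),
               c(log2(20), log2(20)))
  expect_equal(unname(lg$information["pos13"]), log2(20) - 1)  # 2 equal aa
  # uniform 20-residue column carries no information
  unif <- data.frame(aa12 = sort(rownames(lg$freq)), aa13 = "A",
                     aa16 = "A")
  expect_equal(unname(build_logo(unif)$information["pos12"]), 0)
  # single member: maximal information everywhere
  one <- build_logo(data.frame(aa12 = "S", aa13 = "N", aa16 = "E"))
  expect_equal(unname(one$information), rep(log2(20), 3),
               tolerance = 1e-12)
  expect_error(build_logo(data.frame(aa12 = character(0),
                                     aa13 = character(0),
                                     aa16 = character(0))), "empty")
  expect_error(build_logo(data.frame(aa12 = "*", aa13 = "A", aa16 = "A")),
               "[Ss]top")
})

test_that("code-table derivation ranks by specificity with stated ties", {
  st <- make_score_table(rbind(
    c(0, 0, 7.0, 0.5),      # THE: gap 6.5  <- top for (3, G)
    c(0, 0, 6.8, 1.0),      # gap 5.8
    c(6.0, 0, 0, 1.0)),     # A-specific
    repeat_id = 3, trms = c("THE", "SNE", "PHQ"))
  h <- select_hits(st)
  ct <- derive_code_table(h, repeats = 3)
  expect_equal(ct$trm[ct$base == "G"], "THE")
  expect_equal(ct$trm[ct$base == "A"], "PHQ")
  expect_equal(ct$trm[ct$base == "C"], "---")   # empty cell
  # equal specificity and max score: lexicographically smaller TRM wins
  tie <- make_score_table(rbind(c(0, 0, 6, 0), c(0, 0, 6, 0)),
                          repeat_id = 5, trms = c("SWD", "SGD"))
  ct2 <- derive_code_table(select_hits(tie), repeats = 5)
  expect_equal(ct2$trm[ct2$base == "G"], "SGD")
  # wild-type marker
  wt <- make_score_table(rbind(c(0, 0, 9, 0)), repeat_id = 7,
                         trms = "SNE")
  ct3 <- derive_code_table(select_hits(wt), repeats = 7)
  expect_true(ct3$wildtype[ct3$base == "G"])
  expect_false(any(ct3$wildtype[ct3$base != "G"]))
})

test_that("code tables round-trip through TSV", {
  ct <- derive_code_table(select_hits(make_score_table(
    rbind(c(0, 0, 7, 0.5)), repeat_id = 3, trms = "THE")), repeats = 1:8)
  path <- tempfile(fileext = ".tsv")
  write_code_table(ct, path)
  back <- read_code_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ct))
})

test_that("the packaged code table contains the published design codes", {
  ct <- default_code_table()
  expect_equal(nrow(ct), 32)
  entry <- function(r, b) ct$trm[ct$repeat_id == r & ct$base == b]
  expect_equal(entry(3, "G"), "THE")
  expect_equal(entry(4, "C"), "TFR")
  expect_equal(entry(1, "C"), "QFR")
  expect_equal(entry(2, "A"), "VFQ")
  expect_equal(entry(7, "U"), "NPG")
  expect_true(ct$wildtype[ct$repeat_id == 7 & ct$base == "G"])  # SNE
})
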