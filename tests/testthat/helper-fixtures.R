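# Shared fixtures: all built in code at test time.

# A score table with given per-base score rows; TRMs are generated
# distinct and missense unless supplied.
make_score_table <- function(S, repeat_id = 1, trms = NULL,
                             is_nonsense = NULL) {
  S <- matrix(S, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  n <- nrow(S)
  if (is.null(trms)) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    grid <- expand.grid(aa, aa, aa, stringsAsFactors = FALSE)
    trms <- apply(grid[seq_len(n), ], 1, paste, collapse = "")
  }
  if (is.null(is_nonsense)) is_nonsense <- rep(FALSE, n)
  tab <- data.frame(
    repeat_id = rep(repeat_id, length.out = n),
    aa12 = substr(trms, 1, 1), aa13 = substr(trms, 2, 2),
    aa16 = substr(trms, 3, 3),
    S_A = S[, "A"], S_C = S[, "C"], S_G = S[, "G"], S_U = S[, "U"],
    stringsAsFactors = FALSE
  )
  tab$n_bases_observed <- rowSums(!is.na(S))
  tab$specificity <- pufcode::specificity_scores(S)
  tab$is_nonsense <- is_nonsense
  tab$low_input <- FALSE
  tab$missing_base <- tab$n_bases_observed < 2
  class(tab) <- c("puf_scores", "data.frame")
  tab
}

# Count table row(s) for explicit variants.
make_counts <- function(repeat_id, aa12, aa13, aa16, base, pool, count) {
  data.frame(repeat_id = repeat_id, aa12 = aa12, aa13 = aa13, aa16 = aa16,
             base = base, pool = pool, count = count,
             stringsAsFactors = FALSE)
}

# A targeted-screen-sized sub-library of a truth model: every specific
# variant plus samples of the other classes (mirrors a targeted screen's
# ~250-candidate pools per repeat).
targeted_subset <- function(truth, n_broad = 100, n_dead = 80,
                            n_nonsense = 40, seed = 99) {
  idx <- pufcode:::with_seed(seed, c(
    which(truth$class == "specific"),
    sample(which(truth$class == "broad"), n_broad),
    sample(which(truth$class == "dead" & !truth$is_nonsense), n_dead),
    sample(which(truth$is_nonsense), n_nonsense)
  ))
  sub <- truth[sort(idx), , drop = FALSE]
  attr(sub, "config") <- attr(truth, "config")
  class(sub) <- class(truth)
  sub
}

# Naive per-read counting oracle: decodes one read at a time with string
# operations only, independent of the vectorized pipeline.
naive_count_oracle <- function(reads, layout) {
  counts <- new.env()
  discarded <- 0L
  gc_table <- Biostrings::GENETIC_CODE
  for (rd in reads) {
    if (nchar(rd) < layout$read_length ||
        substr(rd, 1, 10) != layout$common_prefix) {
      discarded <- discarded + 1L; next
    }
    tag <- substr(rd, 11, 10 + layout$tag_length)
    hit <- which(layout$repeat_tags == tag)
    if (length(hit) != 1) { discarded <- discarded + 1L; next }
    region <- substr(rd, layout$var_offset + 1, layout$var_offset + 16)
    if (grepl("[^ACGT]", region)) { discarded <- discarded + 1L; next }
    base <- layout$base_code[[substr(region, 1, 1)]]
    aa <- character(5)
    for (j in 1:5) {
      cod <- substr(region, 2 + 3 * (j - 1), 4 + 3 * (j - 1))
      aa[j] <- gc_table[[cod]]
    }
    key <- paste(names(layout$repeat_tags)[hit], aa[1], aa[2], aa[5], base,
                 sep = "|")
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  list(counts = as.list(counts), discarded = discarded)
}
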