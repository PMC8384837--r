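#' Cognate PUF repeat for an RNA position
#'
#' A PUF domain binds its 8-mer site in antiparallel register: repeat i
#' contacts base 9 - i, so repeat 1 reads position 8 and repeat 8 reads
#' position 1.
#'
#' @param position RNA position(s), 1-8 (5' to 3').
#' @return Integer repeat index/indices.
#' @export
cognate_repeat <- function(position) {
  if (any(is.na(position)) || any(position < 1 | position > 8))
    stop("`position` must be in 1..8")
  as.integer(9 - position)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars (e.g. 8-mer RNA targets).
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Wild-type Pumilio-1 recognition site
#'
#' @return The 8-mer `"UGUAAAUA"` (nanos response element core).
#' @export
wildtype_site <- function() "UGUAAAUA"

#' Wild-type site plus all single-base substitutions
#'
#' The RNA modules of a per-repeat selection panel: the wild-type 8-mer
#' and its 24 single-base substitution variants (25 sequences), so every
#' position can present each of the four bases.
#'
#' @param site Reference 8-mer (default [wildtype_site()]).
#' @return Character vector of 25 distinct 8-mers, wild type first.
#' @export
rna_modules <- function(site = wildtype_site()) {
  s <- strsplit(site, "")[[1]]
  out <- site
  for (p in seq_along(s)) for (b in setdiff(RNA_BASES, s[p])) {
    v <- s; v[p] <- b
    out <- c(out, paste(v, collapse = ""))
  }
  out
}

#' Selection conditions of a full per-repeat screen
#'
#' One selection culture per (repeat, varied cognate base): 8 repeats x 4
#' bases = 32 conditions, each pairing a repeat's TRM library with the RNA
#' site carrying that base at the repeat's cognate position.
#'
#' @param repeats Repeat indices (default 1-8).
#' @param site Reference 8-mer.
#' @return `data.frame` with `repeat_id`, `base`, `position` and the
#'   varied `rna` sequence.
#' @export
screen_conditions <- function(repeats = 1:8, site = wildtype_site()) {
  grid <- expand.grid(repeat_id = as.integer(repeats), base = RNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$repeat_id, grid$base), , drop = FALSE]
  rownames(grid) <- NULL
  grid$position <- 9L - grid$repeat_id
  grid$rna <- vapply(seq_len(nrow(grid)), function(i) {
    s <- strsplit(site, "")[[1]]
    s[grid$position[i]] <- grid$base[i]
    paste(s, collapse = "")
  }, character(1))
  grid
}

#' Design a PUF domain against an 8-mer RNA target
#'
#' For every position where the target differs from the wild-type site,
#' the cognate repeat's TRM is substituted with the code-table entry for
#' the target base at that repeat. Positions whose code-table cell is
#' `"---"` are reported as gaps (the design is still returned). Unchanged
#' positions keep the wild-type TRM.
#'
#' @param target 8-mer RNA target (A/C/G/U).
#' @param code Code table (default [default_code_table()]).
#' @param site Wild-type site (default [wildtype_site()]).
#' @param wt_trms Wild-type TRMs per repeat.
#' @return Object of class `"puf_design"`: list with `target`, `site`,
#'   `substitutions` (named character vector, TRM per substituted repeat),
#'   `gaps` (positions with no code-table entry), `n_substitutions` and
#'   the full per-repeat TRM assignment `trms`.
#' @export
design_puf <- function(target, code = default_code_table(),
                       site = wildtype_site(), wt_trms = wildtype_trms()) {
  if (nchar(target) != 8 ||
      !all(strsplit(target, "")[[1]] %in% RNA_BASES))
    stop("`target` must be an 8-mer over A/C/G/U")
  t_chr <- strsplit(target, "")[[1]]
  s_chr <- strsplit(site, "")[[1]]
  subs <- character(0); gaps <- integer(0)
  trms <- wt_trms
  for (p in which(t_chr != s_chr)) {
    r <- cognate_repeat(p)
    entry <- code$trm[code$repeat_id == r & code$base == t_chr[p]]
    if (length(entry) == 0 || entry == "---") {
      gaps <- c(gaps, p)
    } else {
      subs[as.character(r)] <- entry
      trms[as.character(r)] <- entry
    }
  }
  structure(list(target = target, site = site,
                 substitutions = subs, gaps = gaps,
                 n_substitutions = length(subs), trms = trms),
            class = "puf_design")
}

#' @export
print.puf_design <- function(x, ...) {
  cat("PUF design for target", x$target, "(site", paste0(x$site, ")\n"))
  if (x$n_substitutions > 0)
    cat("  substitutions:",
        paste0("R", names(x$substitutions), ":", x$substitutions,
               collapse = ", "), "\n")
  else cat("  no substitutions (target equals site)\n")
  if (length(x$gaps) > 0)
    cat("  uncovered positions (no code entry):",
        paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Per-position sampling probabilities of the programmed random block
#'
#' The published per-position base probabilities used to program the
#' random block of the oligo array, in sampling alphabet order A, T, G, C
#' (T is sampled internally and emitted as U). Each position favours
#' bases related to the target set so the pool is enriched for near-target
#' off-targets.
#'
#' @return 8 x 4 numeric matrix, rows `pos1`..`pos8`, columns
#'   A/T/G/C; rows sum to 1.
#' @export
array_position_probs <- function() {
  m <- rbind(
    pos1 = c(0.10, 0.70, 0.10, 0.10),
    pos2 = c(0.10, 0.49, 0.31, 0.10),
    pos3 = c(0.10, 0.35, 0.45, 0.10),
    pos4 = c(0.70, 0.10, 0.10, 0.10),
    pos5 = c(0.49, 0.10, 0.10, 0.31),
    pos6 = c(0.35, 0.10, 0.45, 0.10),
    pos7 = c(0.35, 0.45, 0.10, 0.10),
    pos8 = c(0.54, 0.10, 0.10, 0.26)
  )
  colnames(m) <- c("A", "T", "G", "C")
  m
}

#' Default 16-target panel
#'
#' Sixteen 8-mer targets differing from the wild-type site by 1, 2, 2, 3
#' (x8), 4 (x3), 5 and 6 bases. The panel contains the target sequences
#' reported for redesigned Pumilio-1 domains (UGUACGUA, UUUAAAAC, UUGAAAUC, UGUACGAC);
#' the remaining entries are synthetic stand-ins constructed to match the
#' published Hamming-distance spectrum, and any 16 user targets may be
#' supplied to [generate_array()] instead.
#'
#' @return Character vector of 16 8-mers.
#' @export
default_targets <- function() {
  c("UGUACAUA",                                    # 1 change
    "UGUACGUA", "UAGAAAUA",                        # 2 changes
    "UUUAAAAC", "UUGAAAUC", "UCUAAGUC", "UGCACGUA",
    "UGAACGUA", "GGUAACUC", "UGUCCGUA", "AGUAAGUG",# 3 changes (x8)
    "UGUACGAC", "CGUGAAGC", "UCUGCGUA",            # 4 changes (x3)
    "UCGACGUG",                                    # 5 changes
    "CAUACGAC")                                    # 6 changes
}

#' Generate the probabilistic RNA oligo array
#'
#' Emits a fixed block — `n_wt` copies of the wild-type sequence and
#' `n_each` copies of each of the 16 targets (900 elements under the
#' defaults) — plus `n_random` programmed random sequences drawn
#' position-independently from the published per-position probability
#' vectors (1,000 under the defaults), for 1,900 elements in all.
#' Sampling uses the DNA alphabet internally; all emitted sequences are in
#' the RNA alphabet. Deterministic per seed.
#'
#' @param targets Character vector of 16 target 8-mers.
#' @param site Wild-type 8-mer.
#' @param n_wt,n_each Copies of the wild type and of each target.
#' @param n_random Number of programmed random sequences.
#' @param probs Per-position probability matrix (see
#'   [array_position_probs()]).
#' @param seed Integer seed.
#' @return `data.frame` of class `"puf_array"`: `seq` (RNA alphabet) and
#'   `category` (`"wildtype"`, `"target_01"`.., `"programmed_random"`);
#'   attributes `seed`, `probs`.
#' @export
generate_array <- function(targets = default_targets(),
                           site = wildtype_site(),
                           n_wt = 20, n_each = 55, n_random = 1000,
                           probs = array_position_probs(), seed = 1L) {
  if (length(targets) != 16) stop("exactly 16 target sequences required")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("probability vectors must each sum to 1")
  fixed <- data.frame(
    seq = c(rep(site, n_wt), rep(targets, each = n_each)),
    category = c(rep("wildtype", n_wt),
                 rep(sprintf("target_%02d", seq_along(targets)),
                     each = n_each)),
    stringsAsFactors = FALSE
  )
  rand <- with_seed(seed, {
    cols <- lapply(seq_len(nrow(probs)), function(p)
      sample(colnames(probs), n_random, replace = TRUE, prob = probs[p, ]))
    do.call(paste0, cols)
  })
  rand <- chartr("T", "U", rand)
  out <- rbind(fixed, data.frame(seq = rand,
                                 category = "programmed_random",
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "probs") <- probs
  class(out) <- c("puf_array", "data.frame")
  out
}

#' Write an oligo array as FASTA plus a TSV manifest
#'
#' Sequences are written in the RNA alphabet with
#' [Biostrings::writeXStringSet()]; the manifest records sequence,
#' category and element index.
#'
#' @param array A [generate_array()] result.
#' @param fasta_path,manifest_path Output paths (either may be `NULL`).
#' @return Invisibly, the array.
#' @export
write_array_fasta <- function(array, fasta_path = NULL,
                              manifest_path = NULL) {
  if (!is.null(fasta_path)) {
    rna <- Biostrings::RNAStringSet(array$seq)
    names(rna) <- sprintf("elem%04d|%s", seq_len(nrow(array)),
                          array$category)
    Biostrings::writeXStringSet(rna, fasta_path)
  }
  if (!is.null(manifest_path)) {
    man <- data.frame(element = seq_len(nrow(array)), array,
                      stringsAsFactors = FALSE)
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(array)
}

#' Register-shift candidate 8-mers
#'
#' If a designed domain binds shifted by one base toward the 3' flank, its
#' enrichment should resemble the three 8-mers sharing the target's seven
#' 5' bases but differing at position 8; a two-base shift implicates the
#' nine 8-mers sharing the six 5' bases and differing at both positions 7
#' and 8. Mirrored definitions apply at the 5' end (differing at position
#' 1, or at positions 1 and 2).
#'
#' @param target 8-mer target.
#' @param shift 1 or 2.
#' @param end `"3p"` (default) or `"5p"`.
#' @return Character vector of candidate 8-mers (3 for shift 1, 9 for
#'   shift 2), disjoint from the target.
#' @export
shift_candidates <- function(target, shift, end = c("3p", "5p")) {
  end <- match.arg(end)
  if (!shift %in% c(1, 2)) stop("`shift` must be 1 or 2")
  s <- strsplit(target, "")[[1]]
  vary <- if (end == "3p") {
    if (shift == 1) list(p8 = 8) else list(p7 = 7, p8 = 8)
  } else {
    if (shift == 1) list(p1 = 1) else list(p1 = 1, p2 = 2)
  }
  alt <- lapply(vary, function(p) setdiff(RNA_BASES, s[p]))
  combos <- expand.grid(alt, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  out <- apply(combos, 1, function(row) {
    v <- s
    v[unlist(vary)] <- unlist(row)
    paste(v, collapse = "")
  })
  unname(out)
}

#' Rank RNA sequences from selection scores
#'
#' Excludes flagged artifact sequences (sequences enriched independently
#' of the substituted TRMs, hence reporter activation not due to a
#' three-hybrid interaction), then ranks the remaining RNAs by mean
#' replicate interaction score. Reports the rank of the intended target
#' and of the wild-type sequence, and the top two non-target sequences.
#' Replicates whose orderings disagree (non-positive rank correlation)
#' raise a discordance flag; the ranking stays mean-based.
#'
#' @param scores `data.frame` with column `seq` and one numeric score
#'   column per replicate.
#' @param target Intended target 8-mer.
#' @param wildtype Wild-type 8-mer.
#' @param exclude Artifact sequences to remove (default `"UCCGACUA"`).
#' @return List of class `"puf_ranking"`: `ranking` (data.frame sorted by
#'   mean score), `target_rank`, `wildtype_rank`, `top_nontarget` (up to
#'   2 sequences), `excluded`, `discordant`.
#' @export
evaluate_selection <- function(scores, target, wildtype = wildtype_site(),
                               exclude = "UCCGACUA") {
  rep_cols <- setdiff(names(scores), "seq")
  if (length(rep_cols) < 1) stop("no replicate score columns")
  kept <- scores[!scores$seq %in% exclude, , drop = FALSE]
  if (nrow(kept) == 0) stop("no sequences remain after exclusion")
  smat <- as.matrix(kept[, rep_cols, drop = FALSE])
  kept$mean_score <- rowMeans(smat)
  discordant <- FALSE
  if (length(rep_cols) >= 2) {
    for (i in seq_len(length(rep_cols) - 1))
      for (j in seq(i + 1, length(rep_cols)))
        if (stats::cor(smat[, i], smat[, j], method = "spearman") <= 0)
          discordant <- TRUE
  }
  ranking <- kept[order(-kept$mean_score, kept$seq), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  rank_of <- function(s) {
    r <- ranking$rank[ranking$seq == s]
    if (length(r) == 0) NA_integer_ else r[1]
  }
  non_target <- ranking$seq[ranking$seq != target]
  structure(list(
    ranking = ranking,
    target_rank = rank_of(target),
    wildtype_rank = rank_of(wildtype),
    top_nontarget = utils::head(non_target, 2),
    excluded = intersect(unique(scores$seq), exclude),
    discordant = discordant
  ), class = "puf_ranking")
}

#' @export
print.puf_ranking <- function(x, ...) {
  cat("Selection ranking over", nrow(x$ranking), "sequences")
  if (length(x$excluded))
    cat(" (excluded:", paste(x$excluded, collapse = ", "), ")")
  cat("\n  target rank   :", x$target_rank, "\n")
  cat("  wild-type rank:", x$wildtype_rank, "\n")
  cat("  top non-target:", paste(x$top_nontarget, collapse = ", "), "\n")
  if (x$discordant) cat("  NOTE: replicates rank-discordant\n")
  invisible(x)
}
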