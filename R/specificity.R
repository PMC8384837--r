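#' Select base-specific hits from a score table
#'
#' A hit is a missense variant whose maximal per-base interaction score
#' strictly exceeds `s_min` and whose specificity score strictly exceeds
#' `d_min` (defaults 5 and 4). Nonsense rows are excluded. The preferred
#' base is the argmax base.
#'
#' @param scores A [interaction_scores()] table.
#' @param s_min Interaction-score threshold (strict).
#' @param d_min Specificity-score threshold (strict).
#' @return The hit rows with columns `preferred_base` and `max_score`
#'   added; attributes `s_min`, `d_min`.
#' @export
select_hits <- function(scores, s_min = 5, d_min = 4) {
  smat <- as.matrix(scores[, paste0("S_", RNA_BASES)])
  mx <- suppressWarnings(apply(smat, 1, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- NA_real_
  keep <- !scores$is_nonsense & !is.na(mx) & mx > s_min &
    !is.na(scores$specificity) & scores$specificity > d_min
  hits <- scores[keep, , drop = FALSE]
  hmat <- smat[keep, , drop = FALSE]
  hits$max_score <- mx[keep]
  hits$preferred_base <- RNA_BASES[apply(hmat, 1, which.max)]
  rownames(hits) <- NULL
  attr(hits, "s_min") <- s_min
  attr(hits, "d_min") <- d_min
  class(hits) <- c("puf_hits", "data.frame")
  hits
}

#' Hierarchically cluster hits by their four-base score profile
#'
#' Rows are normalized by their row maximum, then clustered by
#' average-linkage agglomerative clustering on Euclidean distances. The
#' tree is cut at the smallest number of clusters at which every cluster
#' is pure with respect to preferred base, so variants sharing a base
#' specificity group together. Rows are sorted canonically (by repeat and
#' TRM) first, making the result invariant to input row order.
#'
#' @param hits A [select_hits()] result with all four base scores
#'   observed.
#' @param method Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return `hits` (canonically sorted) with an integer `cluster` column,
#'   numbered in order of first appearance; attribute `hclust` holds the
#'   dendrogram.
#' @export
cluster_hits <- function(hits, method = "average") {
  smat <- as.matrix(hits[, paste0("S_", RNA_BASES)])
  ok <- rowSums(!is.na(smat)) == 4
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) < 2) stop("need at least 2 hits with all four base scores")
  ord <- order(hits$repeat_id, hits$aa12, hits$aa13, hits$aa16)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  x <- normalize_scores(as.matrix(hits[, paste0("S_", RNA_BASES)]))
  hc <- stats::hclust(stats::dist(x), method = method)
  pref <- hits$preferred_base
  assign <- rep(1L, nrow(hits))
  for (k in seq(length(unique(pref)), nrow(hits))) {
    assign <- stats::cutree(hc, k = k)
    pure <- all(vapply(split(pref, assign),
                       function(p) length(unique(p)) == 1, logical(1)))
    if (pure) break
  }
  hits$cluster <- as.integer(match(assign, unique(assign)))
  attr(hits, "hclust") <- hc
  hits
}

#' Subgroup a cluster by amino-acid property signatures
#'
#' Clusters with more than `max_plain` members are partitioned by the
#' physico-chemical class signature (see [aa_property_class()]) of the
#' base-contacting residues 12 and 16; smaller clusters stay as one group.
#'
#' @param members `data.frame` of cluster members with `aa12`, `aa16`.
#' @param max_plain Size above which subgrouping triggers (default 10).
#' @param classes Optional property-class override passed to
#'   [aa_property_class()].
#' @return `members` with columns `signature` and integer `subgroup`.
#' @export
subgroup_by_property <- function(members, max_plain = 10, classes = NULL) {
  sig <- paste(aa_property_class(members$aa12, classes),
               aa_property_class(members$aa16, classes), sep = "/")
  members$signature <- sig
  members$subgroup <- if (nrow(members) > max_plain)
    as.integer(match(sig, unique(sig))) else 1L
  members
}

#' Position frequency matrix and information content for a TRM set
#'
#' Per randomized position (12, 13, 16): the amino-acid frequency vector
#' over the member TRMs and the information content in bits,
#' `log2(20) - H` where `H` is the Shannon entropy of the frequencies.
#' Stop-containing variants are rejected.
#'
#' @param members `data.frame` with `aa12`, `aa13`, `aa16`.
#' @return List of class `"puf_logo"`: `freq` (20 x 3 matrix, columns
#'   `pos12`, `pos13`, `pos16`), `information` (bits per position), `n`.
#' @export
build_logo <- function(members) {
  if (nrow(members) == 0) stop("empty variant set")
  aa20 <- sort(setdiff(names(canonical_nnk_codons()), "*"))
  cols <- c(aa12 = "pos12", aa13 = "pos13", aa16 = "pos16")
  if (any(unlist(members[, names(cols)]) == "*"))
    stop("stop-containing variants cannot enter a logo")
  freq <- vapply(names(cols), function(cl) {
    as.numeric(table(factor(members[[cl]], levels = aa20))) / nrow(members)
  }, numeric(length(aa20)))
  dimnames(freq) <- list(aa20, unname(cols))
  info <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(freq = freq, information = info, n = nrow(members)),
            class = "puf_logo")
}

#' @export
print.puf_logo <- function(x, ...) {
  cat("Sequence logo over", x$n, "TRMs\n")
  cat("  information (bits):",
      paste(names(x$information), round(x$information, 2), sep = "=",
            collapse = " "), "\n")
  top <- apply(x$freq, 2, function(p) names(p)[which.max(p)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Wild-type Pumilio-1 TRMs per repeat
#'
#' The natural tripartite recognition motifs of the human Pumilio-1 PUF
#' domain, one per repeat, for the UGUAAAUA site (repeat i contacts base
#' 9 - i): CRQ recognizing A, NYQ recognizing U and SNE recognizing G.
#' Configurable; the default is assembled from the natural recognition
#' codes reported for this domain.
#'
#' @return Named character vector (names `"1"`..`"8"`).
#' @export
wildtype_trms <- function() {
  c(`1` = "CRQ", `2` = "NYQ", `3` = "CRQ", `4` = "CRQ",
    `5` = "CRQ", `6` = "NYQ", `7` = "SNE", `8` = "NYQ")
}

#' Derive the repeat-by-base recognition-code table from hits
#'
#' For each (repeat, cognate base) cell, the best TRM is the hit with the
#' highest specificity score, ties broken by higher maximal interaction
#' score, then lexicographically smaller TRM. Cells with no hits are
#' rendered `"---"`. Entries matching the repeat's wild-type TRM carry the
#' wild-type marker.
#'
#' @param hits A [select_hits()] (or [cluster_hits()]) result pooled
#'   across repeats and bases.
#' @param wt_trms Wild-type TRM per repeat (see [wildtype_trms()]).
#' @param repeats Repeat rows of the table (default 1-8).
#' @return `data.frame` of class `"puf_code_table"`: `repeat_id`, `base`,
#'   `trm` (`"---"` when absent), `wildtype` (logical).
#' @export
derive_code_table <- function(hits, wt_trms = wildtype_trms(),
                              repeats = 1:8) {
  grid <- expand.grid(repeat_id = as.integer(repeats), base = RNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$repeat_id, grid$base), , drop = FALSE]
  rownames(grid) <- NULL
  grid$trm <- "---"
  if (nrow(hits) > 0) {
    hits$trm <- trm_string(hits$aa12, hits$aa13, hits$aa16)
    cell <- paste(hits$repeat_id, hits$preferred_base, sep = "|")
    for (cl in unique(cell)) {
      h <- hits[cell == cl, , drop = FALSE]
      h <- h[order(-h$specificity, -h$max_score, h$trm), , drop = FALSE]
      grid$trm[grid$repeat_id == h$repeat_id[1] &
                 grid$base == h$preferred_base[1]] <- h$trm[1]
    }
  }
  grid$wildtype <- grid$trm != "---" &
    grid$trm == unname(wt_trms[as.character(grid$repeat_id)])
  class(grid) <- c("puf_code_table", "data.frame")
  grid
}

#' Write / read a code table as TSV
#'
#' @param code A code table (`repeat_id`, `base`, `trm`, `wildtype`).
#' @param path TSV file path.
#' @return `path` (write) or the code table (read).
#' @export
write_code_table <- function(code, path) {
  utils::write.table(code, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_code_table
#' @export
read_code_table <- function(path) {
  code <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(repeat_id = "integer",
                                           base = "character",
                                           trm = "character",
                                           wildtype = "logical"))
  class(code) <- c("puf_code_table", "data.frame")
  code
}

#' Packaged reference code table
#'
#' A partial repeat-by-base recognition-code table assembled from the
#' base-specific TRMs reported for the human Pumilio-1 domain (e.g. QFR
#' for C in repeat 1, VFQ for A in repeat 2, THE for G in repeat 3, TFR
#' for C in repeat 4, NPG for U in repeat 7, SNE for G in repeat 7), with
#' the wild-type TRMs filling their cognate cells. Cells without a
#' reported base-specific TRM are `"---"`. No complete machine-readable
#' code table for this domain is available, so this fixture is explicitly
#' partial and user-replaceable via [read_code_table()].
#'
#' @return Code table `data.frame`.
#' @export
default_code_table <- function() {
  read_code_table(system.file("extdata", "code_table_default.tsv",
                              package = "pufcode", mustWork = TRUE))
}
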