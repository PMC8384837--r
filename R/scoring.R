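#' Interaction scores from paired input/selected count tables
#'
#' The interaction score of a variant is the log2 change in its frequency
#' from the input pool to the post-selection pool, with frequencies
#' computed within each (repeat, cognate-base) library per pool — each such
#' library is a separate selection culture. A variant present in the input
#' pool but absent from the selected pool gets a pseudocount of 1 in the
#' selected pool before its frequency is computed (library totals are not
#' altered). Variants absent from the input pool are dropped and recorded
#' in the `dropped` attribute. Variants whose input count falls below
#' `min_input` in any observed library are retained but flagged
#' `low_input`, since unreliable enrichment estimates concentrate among
#' poorly sampled variants.
#'
#' With `wt_normalize = TRUE`, the score of the wild-type (spiked-in) TRM
#' of each library is subtracted from every score in that library, putting
#' separate selection cultures on a common scale.
#'
#' @param input,selected Count tables (see [tally_counts()]) with matching
#'   pool labels `"input"` and `"selected"`.
#' @param min_input QC threshold on input counts (default 10).
#' @param wt_normalize Re-centre each library on the wild-type TRM score.
#' @param wt_trms Named character vector of wild-type TRMs per repeat
#'   (names `"1"`..`"8"`); required when `wt_normalize = TRUE`.
#' @return A score table of class `"puf_scores"`: one row per
#'   (repeat, TRM) with per-base scores `S_A`, `S_C`, `S_G`, `S_U` (`NA`
#'   where unobserved), `n_bases_observed`, `specificity`, `is_nonsense`,
#'   flags `low_input` and `missing_base`, and attribute `dropped`.
#' @export
interaction_scores <- function(input, selected, min_input = 10,
                               wt_normalize = FALSE, wt_trms = NULL) {
  if (nrow(input) == 0) stop("empty input library")
  if (any(input$pool != "input") || any(selected$pool != "selected"))
    stop("pool labels mismatched: expected 'input' and 'selected'")
  key_cols <- c("repeat_id", "aa12", "aa13", "aa16", "base")
  m <- merge(input[, c(key_cols, "count")],
             selected[, c(key_cols, "count")],
             by = key_cols, all = TRUE, suffixes = c("_in", "_sel"))
  m$count_sel[is.na(m$count_sel)] <- 0
  dropped <- m[is.na(m$count_in) | m$count_in == 0, key_cols, drop = FALSE]
  m <- m[!is.na(m$count_in) & m$count_in > 0, , drop = FALSE]
  lib <- paste(m$repeat_id, m$base, sep = "|")
  tot_in <- stats::ave(m$count_in, lib, FUN = sum)
  tot_sel <- stats::ave(m$count_sel, lib, FUN = sum)
  sel_adj <- ifelse(m$count_sel == 0, 1, m$count_sel)
  m$S <- log2((sel_adj / tot_sel) / (m$count_in / tot_in))
  if (wt_normalize) {
    if (is.null(wt_trms)) stop("`wt_trms` required when `wt_normalize`")
    trm <- trm_string(m$aa12, m$aa13, m$aa16)
    is_wt <- trm == unname(wt_trms[as.character(m$repeat_id)])
    wt_s <- tapply(ifelse(is_wt, m$S, NA), lib,
                   function(x) mean(x, na.rm = TRUE))
    ref <- wt_s[lib]
    if (anyNA(ref))
      stop("wild-type TRM missing from library(ies): ",
           paste(unique(lib[is.na(ref)]), collapse = ", "))
    m$S <- m$S - ref
  }
  m$low <- m$count_in < min_input
  vkey <- variant_key(m)
  uk <- unique(vkey)
  idx <- match(vkey, uk)
  tab <- m[match(uk, vkey), c("repeat_id", "aa12", "aa13", "aa16")]
  rownames(tab) <- NULL
  for (b in RNA_BASES) {
    s <- rep(NA_real_, length(uk))
    sel <- m$base == b
    s[idx[sel]] <- m$S[sel]
    tab[[paste0("S_", b)]] <- s
  }
  smat <- as.matrix(tab[, paste0("S_", RNA_BASES)])
  tab$n_bases_observed <- rowSums(!is.na(smat))
  tab$specificity <- specificity_scores(smat)
  tab$is_nonsense <- tab$aa12 == "*" | tab$aa13 == "*" | tab$aa16 == "*"
  tab$low_input <- as.logical(tapply(m$low, idx, any)[as.character(seq_along(uk))])
  tab$missing_base <- tab$n_bases_observed < 2
  attr(tab, "dropped") <- dropped
  class(tab) <- c("puf_scores", "data.frame")
  tab
}

#' Specificity scores
#'
#' The specificity score of a variant is the difference between its highest
#' and second-highest per-base interaction scores, over the observed bases.
#' Rows with fewer than two observed bases are undefined (`NA`); exact ties
#' at the top give 0.
#'
#' @param s Numeric matrix (rows = variants, columns = bases) or a single
#'   numeric vector of per-base scores; `NA` marks unobserved bases.
#' @return Numeric vector of specificity scores (`NA` where undefined).
#' @export
specificity_scores <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  apply(s, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    x <- sort(x, decreasing = TRUE)
    x[1] - x[2]
  })
}

#' Row-normalize per-base scores by the row maximum
#'
#' Each entry is divided by the row maximum, so the maximal entry becomes
#' 1; negative entries are permitted and scale accordingly. All-zero rows
#' are an error (the normalization is undefined).
#'
#' @param s Numeric matrix or vector of per-base scores.
#' @return Normalized matrix (or vector) of the same shape.
#' @export
normalize_scores <- function(s) {
  vec <- is.null(dim(s))
  if (vec) s <- matrix(s, nrow = 1)
  mx <- apply(s, 1, max, na.rm = TRUE)
  if (any(mx == 0)) stop("row maximum is 0; normalization undefined")
  out <- s / mx
  if (vec) out[1, ] else out
}

#' Nonsense false-positive rate
#'
#' The fraction of nonsense variants with any positive interaction score.
#' Since nonsense variants cannot bind, this estimates the rate at which
#' loss-of-function variants appear spuriously enriched.
#'
#' @param scores A [interaction_scores()] table.
#' @return Fraction in `[0, 1]`.
#' @export
nonsense_fpr <- function(scores) {
  ns <- scores[scores$is_nonsense, , drop = FALSE]
  if (nrow(ns) == 0) stop("no nonsense rows in score table")
  smat <- as.matrix(ns[, paste0("S_", RNA_BASES)])
  pos <- apply(smat, 1, function(x) any(x > 0, na.rm = TRUE))
  sum(pos) / nrow(ns)
}

#' Pearson correlation between replicate score tables
#'
#' Product-moment correlation over the intersection of scored
#' (variant, base) entries of two replicates.
#'
#' @param a,b Score tables from [interaction_scores()].
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(a, b) {
  key_cols <- c("repeat_id", "aa12", "aa13", "aa16")
  s_cols <- paste0("S_", RNA_BASES)
  m <- merge(a[, c(key_cols, s_cols)], b[, c(key_cols, s_cols)],
             by = key_cols, suffixes = c("_a", "_b"))
  xa <- as.vector(as.matrix(m[, paste0(s_cols, "_a")]))
  xb <- as.vector(as.matrix(m[, paste0(s_cols, "_b")]))
  ok <- !is.na(xa) & !is.na(xb)
  if (sum(ok) < 3) stop("fewer than 3 shared scored entries")
  stats::cor(xa[ok], xb[ok])
}

#' Average score tables across replicates
#'
#' Combines replicate score tables by the per-entry mean of the per-base
#' scores, recomputing specificity and flags on the combined scores.
#'
#' @param tables List of score tables over the same libraries.
#' @return Combined score table of class `"puf_scores"`.
#' @export
combine_scores <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  key_cols <- c("repeat_id", "aa12", "aa13", "aa16")
  s_cols <- paste0("S_", RNA_BASES)
  long <- do.call(rbind, lapply(tables, function(t)
    t[, c(key_cols, s_cols, "is_nonsense", "low_input")]))
  vkey <- variant_key(long)
  uk <- unique(vkey)
  idx <- match(vkey, uk)
  out <- long[match(uk, vkey), c(key_cols, "is_nonsense")]
  rownames(out) <- NULL
  for (b in s_cols)
    out[[b]] <- as.numeric(tapply(long[[b]], idx, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)))
  smat <- as.matrix(out[, s_cols])
  out$n_bases_observed <- rowSums(!is.na(smat))
  out$specificity <- specificity_scores(smat)
  out$low_input <- as.logical(tapply(long$low_input, idx, any))
  out$missing_base <- out$n_bases_observed < 2
  class(out) <- c("puf_scores", "data.frame")
  out
}
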