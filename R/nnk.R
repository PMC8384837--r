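#' NNK degenerate codon set
#'
#' The 32 codons of an NNK randomization scheme (N = A/C/G/T at codon
#' positions 1-2, K = G/T at position 3). NNK covers all 20 amino acids and
#' a single stop codon (TAG), which is why saturation libraries use it.
#'
#' @return Character vector of 32 codons, lexicographically sorted.
#' @export
nnk_codons <- function() {
  nt <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(nt, nt, paste0), c("G", "T"), paste0)))
}

#' Translate nucleotide codons under the standard genetic code
#'
#' @param codons Character vector of 3-nt codons (DNA alphabet).
#' @return Single-letter amino acids; `"*"` for stop. `NA` for codons with
#'   characters outside A/C/G/T.
#' @export
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa
}

# Lexicographically first NNK codon for each amino acid (and for stop).
# Used as the canonical codon when emitting reads; decoding accepts any codon.
canonical_nnk_codons <- function() {
  codons <- nnk_codons()
  aa <- translate_codons(codons)
  vapply(split(codons, aa), min, character(1))
}

#' Enumerate a single-repeat NNK TRM library
#'
#' Enumerates every distinct tripartite recognition motif (TRM; residues 12,
#' 13 and 16 of a PUF repeat) realizable from independent NNK codons at the
#' three randomized positions. Residues 14 and 15 are held at fixed
#' identities. Each TRM carries one canonical codon assignment (the
#' lexicographically first NNK codon per residue); variants containing a
#' stop at any randomized position are flagged as nonsense.
#'
#' The codon space is 32^3 = 32,768; the distinct amino-acid triplets number
#' 21^3 = 9,261 of which 20^3 = 8,000 are missense and 1,261 contain at
#' least one stop.
#'
#' @param repeat_id PUF repeat index, 1-8.
#' @param fixed_aa Fixed residues at positions 14 and 15 (length-2).
#' @return `data.frame` with one row per distinct TRM: `repeat_id`, `aa12`,
#'   `aa13`, `aa16`, `quintet` (residues 12-16), `codon12`, `codon13`,
#'   `codon16`, `is_nonsense`.
#' @export
enumerate_nnk_library <- function(repeat_id, fixed_aa = c("G", "G")) {
  if (length(repeat_id) != 1 || is.na(repeat_id) ||
      repeat_id < 1 || repeat_id > 8 || repeat_id != as.integer(repeat_id)) {
    stop("`repeat_id` must be a single integer in 1..8")
  }
  stopifnot(length(fixed_aa) == 2)
  canon <- canonical_nnk_codons()
  aa <- sort(names(canon))   # 20 aa + "*"
  grid <- expand.grid(aa16 = aa, aa13 = aa, aa12 = aa,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("aa12", "aa13", "aa16")]
  grid <- grid[order(grid$aa12, grid$aa13, grid$aa16), , drop = FALSE]
  rownames(grid) <- NULL
  data.frame(
    repeat_id = as.integer(repeat_id),
    grid,
    quintet = paste0(grid$aa12, grid$aa13, fixed_aa[1], fixed_aa[2], grid$aa16),
    codon12 = unname(canon[grid$aa12]),
    codon13 = unname(canon[grid$aa13]),
    codon16 = unname(canon[grid$aa16]),
    is_nonsense = grid$aa12 == "*" | grid$aa13 == "*" | grid$aa16 == "*",
    stringsAsFactors = FALSE
  )
}

#' Amino-acid property classes used for subgrouping
#'
#' Fixed classification of the 20 amino acids into five physico-chemical
#' classes: positive, negative, aromatic, polar-neutral and hydrophobic.
#'
#' @param aa Character vector of single-letter amino acids.
#' @param classes Optional named character vector overriding the default
#'   class table.
#' @return Character vector of class labels (`NA` for stop or unknown).
#' @export
aa_property_class <- function(aa, classes = NULL) {
  if (is.null(classes)) {
    classes <- c(
      K = "positive", R = "positive", H = "positive",
      D = "negative", E = "negative",
      F = "aromatic", W = "aromatic", Y = "aromatic",
      S = "polar", T = "polar", N = "polar", Q = "polar",
      C = "polar", G = "polar",
      A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
      I = "hydrophobic", M = "hydrophobic", P = "hydrophobic"
    )
  }
  unname(classes[aa])
}
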