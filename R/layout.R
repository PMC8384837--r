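#' Read layout for amplicon decoding
#'
#' Describes the structure of a (pre-merged) sequencing read from a TRM
#' selection library: a 10-nt common plasmid prefix used as an exact-match
#' quality filter, a repeat-specific internal tag used to demultiplex the
#' eight PUF repeats, and a 16-nt variable region whose first base encodes
#' the identity of the varied cognate RNA base and whose remaining 15 nt are
#' the five codons for residues 12-16.
#'
#' The experimental libraries marked the RNA identity through synonymous
#' changes in codons flanking the TRM; the exact synonymous code is not
#' published, so the layout abstracts it into a single identifier base with
#' a configurable decode map (default A->A, C->C, G->G, T->U).
#'
#' @param common_prefix 10-nt common sequence (exact-match filter).
#' @param repeat_tags Named character vector, one unique tag per repeat
#'   (names `"1"`..`"8"`); all tags must share one length and be pairwise
#'   distinct.
#' @param base_code Named character vector mapping the identifier base
#'   (names, DNA alphabet) to the cognate RNA base (values in A/C/G/U);
#'   must be a bijection.
#' @param fixed_codons Codons emitted at the non-randomized residues 14 and
#'   15 (length-2).
#' @return An object of class `"puf_layout"`.
#' @export
read_layout <- function(common_prefix = "ACGGTCAGTC",
                        repeat_tags = default_repeat_tags(),
                        base_code = c(A = "A", C = "C", G = "G", T = "U"),
                        fixed_codons = c("GGT", "GGT")) {
  if (nchar(common_prefix) != 10)
    stop("`common_prefix` must be exactly 10 nt")
  if (is.null(names(repeat_tags)) || anyDuplicated(names(repeat_tags)))
    stop("`repeat_tags` must be uniquely named by repeat index")
  if (length(unique(nchar(repeat_tags))) != 1)
    stop("all repeat tags must have the same length")
  if (anyDuplicated(repeat_tags))
    stop("repeat tags must be pairwise distinct")
  if (anyDuplicated(names(base_code)) || anyDuplicated(base_code) ||
      !setequal(base_code, c("A", "C", "G", "U")))
    stop("`base_code` must be a bijection onto {A,C,G,U}")
  if (length(fixed_codons) != 2 || any(nchar(fixed_codons) != 3))
    stop("`fixed_codons` must be two 3-nt codons")
  tag_len <- nchar(repeat_tags[[1]])
  structure(
    list(
      common_prefix = common_prefix,
      repeat_tags = repeat_tags,
      base_code = base_code,
      fixed_codons = fixed_codons,
      tag_length = tag_len,
      var_offset = 10L + tag_len,      # 0-based offset of the 16-nt region
      read_length = 10L + tag_len + 16L
    ),
    class = "puf_layout"
  )
}

#' Default repeat demultiplexing tags
#'
#' Eight arbitrary, pairwise-distinct 8-nt internal tags (one per PUF
#' repeat) used by the synthetic read emitter and decoder.
#'
#' @return Named character vector of tags, names `"1"`..`"8"`.
#' @export
default_repeat_tags <- function() {
  c(`1` = "ACTGGCAA", `2` = "CGATTGCC", `3` = "GTCAACGG", `4` = "TAGCCATT",
    `5` = "AGGATCCA", `6` = "CATGGTAC", `7` = "GCCATAGG", `8` = "TTACGGCA")
}

#' @export
print.puf_layout <- function(x, ...) {
  cat("PUF read layout\n")
  cat("  common prefix :", x$common_prefix, "\n")
  cat("  repeat tags   :", length(x$repeat_tags), "tags of", x$tag_length,
      "nt\n")
  cat("  base code     :",
      paste(names(x$base_code), x$base_code, sep = "->", collapse = " "),
      "\n")
  cat("  read length   :", x$read_length, "nt\n")
  invisible(x)
}

# identifier base for a cognate RNA base (inverse of base_code)
rna_to_identifier <- function(base, layout) {
  inv <- stats::setNames(names(layout$base_code), layout$base_code)
  unname(inv[base])
}
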