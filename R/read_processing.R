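#' Exact-match common-prefix filter
#'
#' A read passes if and only if its first 10 nt equal the layout's common
#' plasmid sequence exactly; no mismatch is tolerated. Short reads fail.
#'
#' @param reads Character vector of read sequences.
#' @param layout A [read_layout()].
#' @return Logical vector.
#' @export
filter_common_prefix <- function(reads, layout = read_layout()) {
  !is.na(reads) & nchar(reads) >= 10 &
    substr(reads, 1, 10) == layout$common_prefix
}

#' Assign a repeat identifier from the internal tag
#'
#' Matches the repeat-specific tag at its fixed offset (immediately after
#' the common prefix), exactly. Reads whose tag matches no repeat get `NA`.
#'
#' @param reads Character vector of read sequences (assumed to have passed
#'   the prefix filter).
#' @param layout A [read_layout()].
#' @return Integer vector of repeat indices, `NA` where unmatched.
#' @export
demultiplex_repeat <- function(reads, layout = read_layout()) {
  tag <- substr(reads, 11, 10 + layout$tag_length)
  idx <- match(tag, layout$repeat_tags)
  as.integer(names(layout$repeat_tags))[idx]
}

#' Decode a 16-nt variable region
#'
#' The first base is the RNA identifier (mapped to the cognate RNA base
#' through the layout's base code); the following 15 nt are the codons for
#' residues 12 through 16, translated under the standard genetic code. The
#' TRM is the residue triplet (12, 13, 16); a variant is nonsense if any
#' TRM codon is a stop. Regions of the wrong length are discarded as
#' `untranslatable`; regions containing characters outside A/C/G/T
#' (including ambiguity codes such as N) are discarded as `invalid_char`.
#'
#' @param region16 Character vector of 16-nt regions.
#' @param layout A [read_layout()].
#' @return `data.frame` with `base`, `aa12`..`aa16`, `quintet`,
#'   `is_nonsense` and `discard_reason` (`NA` when decoded).
#' @export
decode_variant <- function(region16, layout = read_layout()) {
  n <- length(region16)
  out <- data.frame(base = NA_character_, aa12 = NA_character_,
                    aa13 = NA_character_, aa14 = NA_character_,
                    aa15 = NA_character_, aa16 = NA_character_,
                    quintet = NA_character_, is_nonsense = NA,
                    discard_reason = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  rownames(out) <- NULL
  if (n == 0) return(out[0, , drop = FALSE])
  bad_len <- is.na(region16) | nchar(region16) != 16
  bad_chr <- !bad_len & grepl("[^ACGT]", region16)
  out$discard_reason[bad_len] <- "untranslatable"
  out$discard_reason[bad_chr] <- "invalid_char"
  ok <- !bad_len & !bad_chr
  if (any(ok)) {
    reg <- region16[ok]
    out$base[ok] <- unname(layout$base_code[substr(reg, 1, 1)])
    starts <- c(2, 5, 8, 11, 14)
    aa <- vapply(starts, function(s)
      translate_codons(substr(reg, s, s + 2)), character(sum(ok)))
    aa <- matrix(aa, ncol = 5)
    out$aa12[ok] <- aa[, 1]; out$aa13[ok] <- aa[, 2]
    out$aa14[ok] <- aa[, 3]; out$aa15[ok] <- aa[, 4]
    out$aa16[ok] <- aa[, 5]
    out$quintet[ok] <- apply(aa, 1, paste, collapse = "")
    out$is_nonsense[ok] <- aa[, 1] == "*" | aa[, 2] == "*" | aa[, 5] == "*"
  }
  out
}

#' Decode raw reads into per-read variant assignments
#'
#' Applies, in order: the exact common-prefix filter, repeat
#' demultiplexing by internal tag, and variable-region decoding. Each read
#' either decodes fully or carries exactly one discard reason
#' (`prefix_mismatch`, `tag_unmatched`, `untranslatable`, `invalid_char`).
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (read with [Biostrings::readDNAStringSet()]).
#' @param layout A [read_layout()].
#' @return `data.frame` with one row per read: `repeat_id`, `base`,
#'   `aa12`, `aa13`, `aa16`, `quintet`, `is_nonsense`, `discard_reason`.
#' @export
decode_reads <- function(reads, layout = read_layout()) {
  if (length(reads) == 1 && !is.na(reads) && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  n <- length(reads)
  repeat_id <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  pass <- filter_common_prefix(reads, layout)
  reason[!pass] <- "prefix_mismatch"
  repeat_id[pass] <- demultiplex_repeat(reads[pass], layout)
  unmatched <- pass & is.na(repeat_id)
  reason[unmatched] <- "tag_unmatched"
  ok <- pass & !unmatched
  region <- substr(reads, layout$var_offset + 1, layout$var_offset + 16)
  dec <- decode_variant(ifelse(ok, region, NA_character_), layout)
  reason[ok & !is.na(dec$discard_reason)] <-
    dec$discard_reason[ok & !is.na(dec$discard_reason)]
  decoded <- ok & is.na(dec$discard_reason)
  data.frame(
    repeat_id = ifelse(decoded, repeat_id, NA_integer_),
    base = ifelse(decoded, dec$base, NA_character_),
    aa12 = ifelse(decoded, dec$aa12, NA_character_),
    aa13 = ifelse(decoded, dec$aa13, NA_character_),
    aa16 = ifelse(decoded, dec$aa16, NA_character_),
    quintet = ifelse(decoded, dec$quintet, NA_character_),
    is_nonsense = ifelse(decoded, dec$is_nonsense, NA),
    discard_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Aggregate decoded reads into a count table
#'
#' Read counts for a variant are the sum over all decoded reads matching
#' that (repeat, TRM, cognate base) — synonymous codon spellings of one TRM
#' collapse into a single count. Discarded reads are tallied by reason.
#' The conservation invariant `sum(counts) + discarded == total` always
#' holds.
#'
#' @param decoded A [decode_reads()] result.
#' @param pool Pool label, `"input"` or `"selected"`.
#' @return Count table `data.frame` (`repeat_id`, `aa12`, `aa13`, `aa16`,
#'   `base`, `pool`, `count`) with attributes `total_reads`,
#'   `discarded_reads` and `discard_summary`.
#' @export
tally_counts <- function(decoded, pool = c("input", "selected")) {
  pool <- match.arg(pool)
  keep <- is.na(decoded$discard_reason)
  d <- decoded[keep, , drop = FALSE]
  if (nrow(d) > 0) {
    key <- paste(d$repeat_id, d$aa12, d$aa13, d$aa16, d$base, sep = "|")
    tab <- table(key)
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    counts <- data.frame(
      repeat_id = as.integer(vapply(parts, `[`, "", 1)),
      aa12 = vapply(parts, `[`, "", 2),
      aa13 = vapply(parts, `[`, "", 3),
      aa16 = vapply(parts, `[`, "", 4),
      base = vapply(parts, `[`, "", 5),
      pool = pool,
      count = as.numeric(tab),
      stringsAsFactors = FALSE
    )
    counts <- counts[order(counts$repeat_id, counts$base, counts$aa12,
                           counts$aa13, counts$aa16), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(repeat_id = integer(0), aa12 = character(0),
                         aa13 = character(0), aa16 = character(0),
                         base = character(0), pool = character(0),
                         count = numeric(0), stringsAsFactors = FALSE)
  }
  attr(counts, "total_reads") <- nrow(decoded)
  attr(counts, "discarded_reads") <- sum(!keep)
  attr(counts, "discard_summary") <-
    table(factor(decoded$discard_reason,
                 levels = c("prefix_mismatch", "tag_unmatched",
                            "untranslatable", "invalid_char")))
  counts
}

#' Process a FASTQ pool into a count table
#'
#' Convenience wrapper: [decode_reads()] then [tally_counts()].
#'
#' @inheritParams decode_reads
#' @inheritParams tally_counts
#' @return Count table (see [tally_counts()]).
#' @export
process_fastq <- function(reads, layout = read_layout(),
                          pool = c("input", "selected")) {
  tally_counts(decode_reads(reads, layout), match.arg(pool))
}
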