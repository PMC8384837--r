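# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# TRM string "NYQ" from component columns
trm_string <- function(aa12, aa13, aa16) paste0(aa12, aa13, aa16)

variant_key <- function(df) {
  paste(df$repeat_id, df$aa12, df$aa13, df$aa16, sep = "|")
}

RNA_BASES <- c("A", "C", "G", "U")

#' Write a count table as TSV
#'
#' @param counts Count table (`repeat_id`, `aa12`, `aa13`, `aa16`, `base`,
#'   `pool`, `count`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV file.
#' @return Count table `data.frame`.
#' @export
read_count_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(repeat_id = "integer", aa12 = "character",
                                   aa13 = "character", aa16 = "character",
                                   base = "character", pool = "character",
                                   count = "numeric"))
}
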