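#' Run the full synthetic selection pipeline
#'
#' Chains the stages end to end: build a ground-truth model, simulate
#' input/post-selection pools, emit and re-process FASTQ reads, score
#' interactions and specificity, select hits, build per-cell logos and
#' derive the recognition-code table. Optionally designs PUF domains for
#' configured targets from the derived table. All outputs (TSV/JSON) and
#' a run manifest with seeds and per-stage row counts go to
#' `config$out_dir`; a rerun with the same config reproduces them
#' bit-identically.
#'
#' @param config Named list, or path to a YAML/JSON file. Required
#'   fields: `seed`, `depth`, `out_dir`. Optional: `repeats` (default 1),
#'   `bases` (default all four), `s_min` (5), `d_min` (4), `min_input`
#'   (10), `emit_fastq` (TRUE: route counts through FASTQ emission and
#'   decoding), `error_rate` (0), `truth` (arguments for
#'   [truth_config()]), `design_targets` (8-mers to design against the
#'   derived code table).
#' @return The manifest (named list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("seed", "depth", "out_dir"))
    if (is.null(config[[field]]))
      stop("config missing required field: `", field, "`")
  repeats <- config$repeats %||% 1L
  bases <- config$bases %||% RNA_BASES
  s_min <- config$s_min %||% 5
  d_min <- config$d_min %||% 4
  min_input <- config$min_input %||% 10
  use_fastq <- config$emit_fastq %||% TRUE
  layout <- read_layout()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(
    utils::packageVersion("pufcode")), seed = config$seed,
    depth = config$depth, repeats = repeats, stages = list())

  tcfg <- do.call(truth_config, config$truth %||% list())
  truth <- build_truth_model(tcfg, seed = config$seed, repeats = repeats)
  manifest$stages$truth <- list(n_variants = nrow(truth))

  pools <- simulate_pools(truth, depth = config$depth,
                          seed = config$seed + 1L, bases = bases)
  manifest$stages$simulate <- list(
    n_libraries = length(repeats) * length(bases),
    input_reads = sum(pools$input$count),
    selected_reads = sum(pools$selected$count))

  if (use_fastq) {
    counts <- lapply(c(input = "input", selected = "selected"), function(p) {
      fq <- out(paste0(p, ".fastq"))
      emit_fastq(pools[[p]], layout, path = fq,
                 seed = config$seed + 2L,
                 error_rate = config$error_rate %||% 0)
      ct <- process_fastq(fq, layout, pool = p)
      ct
    })
    manifest$stages$read_processing <- list(
      input_total = attr(counts$input, "total_reads"),
      input_discarded = attr(counts$input, "discarded_reads"),
      selected_total = attr(counts$selected, "total_reads"),
      selected_discarded = attr(counts$selected, "discarded_reads"))
  } else {
    counts <- pools
    counts$input$pool <- "input"; counts$selected$pool <- "selected"
  }
  write_count_table(counts$input, out("counts_input.tsv"))
  write_count_table(counts$selected, out("counts_selected.tsv"))

  scores <- interaction_scores(counts$input, counts$selected,
                               min_input = min_input)
  utils::write.table(scores, out("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$scoring <- list(n_scored = nrow(scores),
                                  n_dropped = nrow(attr(scores, "dropped")))

  hits <- select_hits(scores, s_min = s_min, d_min = d_min)
  utils::write.table(hits, out("hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$hits <- list(n_hits = nrow(hits))

  logos <- list()
  if (nrow(hits) > 0) {
    cell <- paste0("R", hits$repeat_id, "_", hits$preferred_base)
    logos <- lapply(split(hits, cell), build_logo)
    logo_df <- do.call(rbind, lapply(names(logos), function(nm)
      data.frame(cell = nm, position = colnames(logos[[nm]]$freq),
                 information = unname(logos[[nm]]$information),
                 n = logos[[nm]]$n)))
    utils::write.table(logo_df, out("logos.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$stages$logos <- list(n_cells = length(logos))

  code <- derive_code_table(hits, repeats = repeats)
  write_code_table(code, out("code_table.tsv"))
  manifest$stages$code_table <- list(
    n_cells = nrow(code), n_filled = sum(code$trm != "---"))

  if (!is.null(config$design_targets)) {
    designs <- lapply(config$design_targets, design_puf, code = code)
    jsonlite::write_json(
      lapply(designs, function(d) d[c("target", "substitutions",
                                      "gaps", "n_substitutions")]),
      out("designs.json"), auto_unbox = TRUE, pretty = TRUE)
    manifest$stages$design <- list(n_designs = length(designs))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
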