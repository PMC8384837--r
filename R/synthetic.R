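#' Configuration for the ground-truth activity model
#'
#' Parameters of the generative model behind the synthetic selection data.
#' Missense TRMs fall into three classes: `dead` (no binding to any base),
#' `broad` (comparable binding to all four bases) and `specific` (strong
#' binding to exactly one preferred base). Nonsense TRMs are always dead.
#' Activities are in log2-enrichment units, so a variant with activity a
#' grows 2^a-fold relative to a variant with activity 0 during one round of
#' selection.
#'
#' The class proportions and activity locations emulate the observed shape
#' of a TRM deep mutational scan: deleterious nonsense variants centred
#' well below zero, and a bimodal missense distribution in which most
#' variants are dead and a minority are strongly enriched.
#'
#' @param p_specific,p_broad,p_dead Missense class proportions (sum to 1).
#' @param dead_mean,dead_sd Location/spread of dead-class activities.
#' @param dead_ceiling Upper clamp for dead-class activities.
#' @param active_mean,active_sd Location/spread of the preferred-base
#'   activity of specific variants.
#' @param active_cap Upper clamp for non-planted specific activities; keeps
#'   planted entries (see [build_truth_model()]) uniquely on top.
#' @param specific_floor Lower clamp of a specific variant's preferred-base
#'   activity; also the defining threshold of the specific class.
#' @param broad_mean,broad_sd Location/spread of broad-class activities.
#' @param broad_jitter_sd Per-base jitter within a broad variant.
#' @param planted_activity Preferred-base activity assigned to planted
#'   code-table entries.
#' @param planted_off Fixed off-base activity of planted entries; set well
#'   below the dead-class mean so planted entries are maximally specific
#'   by construction (they define the true code-table optimum).
#' @return A list of class `"puf_truth_config"`.
#' @export
truth_config <- function(p_specific = 0.005, p_broad = 0.045, p_dead = 0.95,
                         dead_mean = -5, dead_sd = 1, dead_ceiling = 0,
                         active_mean = 6.5, active_sd = 0.75,
                         active_cap = 8, specific_floor = 5,
                         broad_mean = 4, broad_sd = 0.75,
                         broad_jitter_sd = 0.3,
                         planted_activity = 9, planted_off = -8) {
  p <- c(p_specific, p_broad, p_dead)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class proportions must be nonnegative and sum to 1")
  if (dead_sd < 0 || active_sd < 0 || broad_sd < 0 || broad_jitter_sd < 0)
    stop("spreads must be nonnegative")
  if (specific_floor <= dead_ceiling)
    stop("`specific_floor` must exceed `dead_ceiling`")
  structure(as.list(environment()), class = "puf_truth_config")
}

#' Build a ground-truth activity model for TRM libraries
#'
#' Assigns every TRM of the requested repeat libraries a class and a
#' per-base activity (log2-enrichment units). Deterministic for a fixed
#' seed and configuration.
#'
#' A `planted` table forces chosen (repeat, base) cells to carry a
#' designated specific TRM at activity `config$planted_activity`, above the
#' cap applied to all other specific variants; this yields libraries whose
#' best base-specific TRM is known by construction, the ground truth that
#' code-table recovery is checked against.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @param repeats Repeat indices to generate (default all eight).
#' @param planted Optional `data.frame` with columns `repeat_id`, `base`,
#'   `aa12`, `aa13`, `aa16`.
#' @param noise_sd Standard deviation of independent Gaussian noise added
#'   to every activity after class assignment (default 0).
#' @return Object of class `"puf_truth"`: a `data.frame` with one row per
#'   (repeat, TRM) and columns `class`, `preferred_base` and activities
#'   `act_A`, `act_C`, `act_G`, `act_U`, plus attributes `config` and
#'   `seed`.
#' @export
build_truth_model <- function(config = truth_config(), seed = 1L,
                              repeats = 1:8, planted = NULL,
                              noise_sd = 0) {
  stopifnot(inherits(config, "puf_truth_config"))
  lib <- do.call(rbind, lapply(repeats, enumerate_nnk_library))
  n <- nrow(lib)
  with_seed(seed, {
    cls <- ifelse(lib$is_nonsense, "dead",
                  sample(c("specific", "broad", "dead"), n, replace = TRUE,
                         prob = c(config$p_specific, config$p_broad,
                                  config$p_dead)))
    pref <- ifelse(cls == "specific", sample(RNA_BASES, n, replace = TRUE),
                   NA_character_)
    draw_dead <- function(k)
      pmin(stats::rnorm(k, config$dead_mean, config$dead_sd),
           config$dead_ceiling)
    act <- matrix(draw_dead(4L * n), nrow = n,
                  dimnames = list(NULL, RNA_BASES))
    is_spec <- cls == "specific"
    if (any(is_spec)) {
      on <- pmin(pmax(stats::rnorm(sum(is_spec), config$active_mean,
                                   config$active_sd),
                      config$specific_floor), config$active_cap)
      act[cbind(which(is_spec), match(pref[is_spec], RNA_BASES))] <- on
    }
    is_broad <- cls == "broad"
    if (any(is_broad)) {
      level <- stats::rnorm(sum(is_broad), config$broad_mean, config$broad_sd)
      act[is_broad, ] <- level +
        matrix(stats::rnorm(4L * sum(is_broad), 0, config$broad_jitter_sd),
               ncol = 4)
    }
    if (!is.null(planted)) {
      key <- variant_key(lib)
      pkey <- variant_key(planted)
      idx <- match(pkey, key)
      if (anyNA(idx)) stop("planted TRM not present in enumerated library")
      cls[idx] <- "specific"
      pref[idx] <- planted$base
      act[idx, ] <- config$planted_off
      act[cbind(idx, match(planted$base, RNA_BASES))] <-
        config$planted_activity
    }
    if (noise_sd > 0)
      act <- act + matrix(stats::rnorm(4L * n, 0, noise_sd), nrow = n)
    truth <- data.frame(
      lib[, c("repeat_id", "aa12", "aa13", "aa16", "is_nonsense")],
      class = cls, preferred_base = pref,
      act_A = act[, "A"], act_C = act[, "C"],
      act_G = act[, "G"], act_U = act[, "U"],
      stringsAsFactors = FALSE
    )
    attr(truth, "config") <- config
    attr(truth, "seed") <- seed
    class(truth) <- c("puf_truth", "data.frame")
    truth
  })
}

#' Simulate paired input/selected pools for one library
#'
#' Low-level single-library simulator over plain vectors. The input pool is
#' a multinomial draw of size `depth` from the input frequencies; the
#' selected pool is a multinomial draw with sampling weight proportional to
#' `f * 2^activity` (one round of exponential growth), so the expected
#' log2 frequency ratio of a variant equals its activity minus a
#' library-wide constant, and expected score differences equal activity
#' differences. With `sampling = "expected"` the (possibly fractional)
#' expected counts `depth * p` are returned instead of draws — the
#' noise-free limit used for exact parameter-recovery checks.
#'
#' @param activity Numeric vector of variant activities (log2 units).
#' @param input_freq Input frequencies (nonnegative, summing to 1; default
#'   uniform).
#' @param depth Reads per pool.
#' @param seed Integer seed (ignored for `"expected"` sampling).
#' @param sampling `"multinomial"` (default) or `"expected"`.
#' @return List with numeric vectors `input` and `selected` of counts.
#' @export
simulate_library_pools <- function(activity, input_freq = NULL, depth,
                                   seed = NULL,
                                   sampling = c("multinomial", "expected")) {
  sampling <- match.arg(sampling)
  n <- length(activity)
  if (n == 0) stop("empty library")
  if (depth <= 0) stop("`depth` must be positive")
  if (is.null(input_freq)) input_freq <- rep(1 / n, n)
  if (length(input_freq) != n || any(input_freq < 0))
    stop("`input_freq` must be nonnegative and match `activity` in length")
  input_freq <- input_freq / sum(input_freq)
  w <- input_freq * 2^activity
  p_sel <- w / sum(w)
  if (sampling == "expected") {
    list(input = depth * input_freq, selected = depth * p_sel)
  } else {
    with_seed(seed, list(
      input = as.numeric(stats::rmultinom(1, depth, input_freq)),
      selected = as.numeric(stats::rmultinom(1, depth, p_sel))
    ))
  }
}

#' Simulate input and post-selection pools for a truth model
#'
#' Runs [simulate_library_pools()] for every (repeat, cognate-base) library
#' of a ground-truth model — each such library is one separate three-hybrid
#' selection culture — and returns tidy count tables.
#'
#' @param truth A [build_truth_model()] result.
#' @param depth Reads per pool per library.
#' @param seed Integer seed.
#' @param input_freq Optional per-variant input frequencies applied to each
#'   library of a repeat (length = variants per repeat); default uniform.
#' @param bases Cognate RNA bases to simulate (default all four).
#' @param sampling Passed to [simulate_library_pools()].
#' @return List of two count tables (`input`, `selected`) with columns
#'   `repeat_id`, `aa12`, `aa13`, `aa16`, `base`, `pool`, `count`.
#' @export
simulate_pools <- function(truth, depth, seed = 1L, input_freq = NULL,
                           bases = RNA_BASES,
                           sampling = c("multinomial", "expected")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(truth, "puf_truth"))
  pieces_in <- list(); pieces_sel <- list()
  k <- 0L
  for (r in sort(unique(truth$repeat_id))) {
    tr <- truth[truth$repeat_id == r, , drop = FALSE]
    for (b in bases) {
      k <- k + 1L
      pools <- simulate_library_pools(
        tr[[paste0("act_", b)]], input_freq, depth,
        seed = if (is.null(seed)) NULL else seed + 1000L * k,
        sampling = sampling
      )
      base_df <- data.frame(tr[, c("repeat_id", "aa12", "aa13", "aa16")],
                            base = b, stringsAsFactors = FALSE)
      pieces_in[[k]] <- data.frame(base_df, pool = "input",
                                   count = pools$input)
      pieces_sel[[k]] <- data.frame(base_df, pool = "selected",
                                    count = pools$selected)
    }
  }
  list(input = do.call(rbind, pieces_in),
       selected = do.call(rbind, pieces_sel))
}

#' Emit a count table as synthetic FASTQ reads
#'
#' Writes exactly one read per count unit. Each read is the common prefix,
#' the repeat tag, the RNA identifier base and the five codons for residues
#' 12-16 (canonical NNK codons for the randomized residues, the layout's
#' fixed codons for residues 14-15). Qualities are a constant Phred "I".
#' An optional uniform substitution error rate corrupts bases at random
#' (seeded); by default reads are error-free and the decode round-trip is
#' exact.
#'
#' @param counts Count table (`repeat_id`, `aa12`, `aa13`, `aa16`, `base`,
#'   `count`); fractional counts are rounded.
#' @param layout A [read_layout()].
#' @param path Optional FASTQ output path; when given, reads are written
#'   with [Biostrings::writeXStringSet()].
#' @param seed Seed for read shuffling / error injection.
#' @param error_rate Per-base substitution probability (default 0).
#' @return Character vector of read sequences (invisibly when `path` is
#'   given).
#' @export
emit_fastq <- function(counts, layout = read_layout(), path = NULL,
                       seed = 1L, error_rate = 0) {
  stopifnot(inherits(layout, "puf_layout"))
  if (any(counts$count < 0)) stop("counts must be nonnegative")
  counts <- counts[round(counts$count) > 0, , drop = FALSE]
  if (nrow(counts) > 0) {
    canon <- canonical_nnk_codons()
    miss <- setdiff(unique(c(counts$aa12, counts$aa13, counts$aa16)),
                    names(canon))
    if (length(miss) > 0)
      stop("variant lacking codon assignment for residue(s): ",
           paste(miss, collapse = ", "))
    tags <- layout$repeat_tags[as.character(counts$repeat_id)]
    if (anyNA(tags)) stop("repeat without a layout tag")
    tmpl <- paste0(layout$common_prefix, tags,
                   rna_to_identifier(counts$base, layout),
                   canon[counts$aa12], canon[counts$aa13],
                   layout$fixed_codons[1], layout$fixed_codons[2],
                   canon[counts$aa16])
    reads <- rep(tmpl, round(counts$count))
  } else reads <- character(0)
  if (error_rate > 0 && length(reads) > 0) {
    reads <- with_seed(seed, {
      m <- do.call(rbind, strsplit(reads, ""))
      hit <- matrix(stats::runif(length(m)) < error_rate, nrow = nrow(m))
      if (any(hit)) {
        nt <- c("A", "C", "G", "T")
        m[hit] <- vapply(m[hit],
                         function(x) sample(setdiff(nt, x), 1), character(1))
      }
      apply(m, 1, paste, collapse = "")
    })
  }
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- if (length(reads)) paste0("read", seq_along(reads))
                  else character(0)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = qual)
    return(invisible(reads))
  }
  reads
}
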