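#' Configuration for an end-to-end pipeline run
#'
#' @param input Path to a JSONL notes file, or a notes data frame, or
#'   `NULL` when `mode = "synthetic"`.
#' @param mode One of `"full-corpus"` (one stratum covering every note),
#'   `"per-note-type"`, `"per-chapter"`, `"both"` (note types and
#'   chapters), or `"synthetic"` (generate the corpus first, then analyze
#'   note types and chapters).
#' @param k_grid Candidate topic numbers for the K scan; `NULL` skips the
#'   scan and uses `k_override`.
#' @param k_override Fixed topic number per stratum when no scan is run
#'   (convention: 17 for a full corpus, 20 for category strata).
#' @param n_runs Replicate fits per stratum (default 5).
#' @param seeds Replicate seeds; default `seed + 0:(n_runs-1)`.
#' @param seed Base seed (default 1).
#' @param n_top Top words per topic cluster (default 10).
#' @param coherence_window Sliding-window width for coherence.
#' @param generator [corpus_config()] used when `mode = "synthetic"`.
#' @param min_docs Minimum documents a stratum needs to be fitted
#'   (default 2).
#' @param output_dir Directory for artifacts; `NULL` writes nothing.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, mode = c("full-corpus", "per-note-type",
                                              "per-chapter", "both", "synthetic"),
                       k_grid = NULL, k_override = 20L, n_runs = 5L,
                       seeds = NULL, seed = 1L, n_top = 10L,
                       coherence_window = 110L, generator = NULL,
                       min_docs = 2L, output_dir = NULL) {
  mode <- match.arg(mode)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  if (!is.null(k_grid) && length(k_grid) == 0L) stop("empty K grid")
  structure(list(
    input = input, mode = mode, k_grid = k_grid,
    k_override = as.integer(k_override), n_runs = as.integer(n_runs),
    seeds = as.integer(seeds), seed = as.integer(seed),
    n_top = as.integer(n_top), coherence_window = as.integer(coherence_window),
    generator = generator, min_docs = as.integer(min_docs),
    output_dir = output_dir
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or generate notes; (2) select social work notes by
#' metadata; (3) drop short and duplicate notes; (4) tokenize and
#' vectorize each stratum; (5) pick K per stratum (scan or override);
#' (6) fit `n_runs` replicate LDA models per stratum; (7) render and label
#' every topic cluster against the SDoH dictionary; (8) pool labels into
#' per-stratum proportions and run the chi-squared word comparison across
#' strata. Every stage's bookkeeping lands in the returned report, and a
#' run is fully reproducible from its config.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: `counts` (notes before/after each
#'   filter and the drop reasons), `cohort` (patients by notes-per-patient
#'   stratum), `strata` (per-stratum document counts and chosen K),
#'   `clusters` (labeled cluster inventory; one row per run x topic),
#'   `proportions` (stratum x label matrix), `chi2` (word-frequency
#'   comparison across strata), `k_scans`, `seeds`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gt <- NULL
  if (config$mode == "synthetic") {
    gen <- config$generator
    if (is.null(gen)) gen <- corpus_config(seed = config$seed)
    syn <- generate_corpus(gen)
    notes <- syn$notes
    gt <- syn$ground_truth
  } else if (is.character(config$input)) {
    notes <- read_notes(config$input)
  } else if (is.data.frame(config$input)) {
    notes <- config$input
  } else stop("stage load: no input notes")

  n_loaded <- nrow(notes)
  social <- select_social_notes(notes)
  n_social <- nrow(social)
  kept <- filter_notes(social)
  drops <- attr(kept, "drop_counts")
  if (nrow(kept) == 0L) stop("stage preprocessing: no notes survive filtering")

  cohort <- summarize_cohort(kept)
  stopwords <- sdoh_stopwords()
  tokens_all <- tokenize_text(kept$text, stopwords)

  strata <- pipeline_strata(kept, config$mode)
  dict <- load_label_dictionary()

  cluster_tabs <- list()
  k_scans <- list()
  strata_info <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < config$min_docs) next
    toks <- tokens_all[idx]
    if (all(lengths(toks) == 0L)) next
    m <- build_dtm(toks, doc_ids = kept$note_id[idx])
    if (!is.null(config$k_grid)) {
      scan <- scan_k(m, toks, config$k_grid, seeds = config$seed,
                     n_top = config$n_top, window = config$coherence_window)
      K <- attr(scan, "selected")
      k_scans[[s]] <- scan
    } else K <- config$k_override
    fits <- run_replicates(m, K, config$seeds)
    cluster_tabs[[s]] <- topic_clusters(fits, category = s, n_top = config$n_top)
    strata_info[[s]] <- data.frame(stratum = s, n_docs = length(idx), K = K,
                                   stringsAsFactors = FALSE)
  }
  if (length(cluster_tabs) == 0L) stop("stage fit: no stratum had enough documents")
  clusters <- do.call(rbind, unname(cluster_tabs))
  clusters <- label_clusters(clusters, dict)
  props <- topic_proportions(clusters, all_labels = names(dict))

  chi2 <- NULL
  # for the word-frequency comparison each document needs one category;
  # a document matching several strata is attributed to the first
  doc_strata <- rep(NA_character_, nrow(kept))
  for (s in rev(names(strata))) doc_strata[strata[[s]]] <- s
  usable <- !is.na(doc_strata) & lengths(tokens_all) > 0L
  if (length(unique(doc_strata[usable])) >= 2L) {
    m_all <- build_dtm(tokens_all[usable], doc_ids = kept$note_id[usable])
    chi2 <- chi2_word_selection(m_all$dtm, doc_strata[usable], stopwords)
  }

  report <- structure(list(
    counts = c(loaded = n_loaded, social = n_social,
               short_dropped = unname(drops["short"]),
               duplicate_dropped = unname(drops["duplicate"]),
               analyzed = nrow(kept)),
    cohort = cohort,
    strata = do.call(rbind, unname(strata_info)),
    clusters = clusters,
    n_clusters = nrow(clusters),
    proportions = props,
    chi2 = chi2,
    k_scans = k_scans,
    seeds = config$seeds,
    ground_truth = gt,
    config = config
  ), class = "pipeline_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# Document index per stratum. A note with codes in several chapters
# contributes to each matching chapter; notes with no mappable code are
# excluded from chapter strata but kept in note-type strata.
pipeline_strata <- function(notes, mode) {
  strata <- list()
  if (mode %in% c("full-corpus")) {
    strata[["all"]] <- seq_len(nrow(notes))
    return(strata)
  }
  if (mode %in% c("per-note-type", "both", "synthetic")) {
    for (tp in note_type_schema()$note_type) {
      idx <- which(notes$note_type == tp)
      if (length(idx)) strata[[tp]] <- idx
    }
  }
  if (mode %in% c("per-chapter", "both", "synthetic")) {
    chapters <- icd10_chapters()
    mapped <- lapply(notes$icd10_codes, function(codes) {
      if (length(codes) == 0L) return(character(0))
      unique(stats::na.omit(map_icd10_chapter(codes, chapters)))
    })
    for (ch in chapters$chapter) {
      idx <- which(vapply(mapped, function(m) ch %in% m, TRUE))
      if (length(idx)) strata[[ch]] <- idx
    }
  }
  strata
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  notes loaded:       %d\n", x$counts[["loaded"]]))
  cat(sprintf("  social work notes:  %d\n", x$counts[["social"]]))
  cat(sprintf("  dropped short:      %d\n", x$counts[["short_dropped"]]))
  cat(sprintf("  dropped duplicate:  %d\n", x$counts[["duplicate_dropped"]]))
  cat(sprintf("  analyzed:           %d\n", x$counts[["analyzed"]]))
  cat(sprintf("  strata fitted:      %d\n", nrow(x$strata)))
  cat(sprintf("  topic clusters:     %d\n", x$n_clusters))
  lab <- x$clusters$label
  cat(sprintf("  labeled clusters:   %d (%.1f%%)\n", sum(!is.na(lab)),
              100 * mean(!is.na(lab))))
  invisible(x)
}

# Write the report artifacts (TSV/JSON) into a directory.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clusters <- report$clusters
  clusters$words <- vapply(clusters$words, paste, "", collapse = " ")
  utils::write.table(clusters, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$proportions, file.path(dir, "proportions.tsv"),
                     sep = "\t", col.names = NA, quote = FALSE)
  if (!is.null(report$chi2)) {
    utils::write.table(report$chi2$proportions,
                       file.path(dir, "word_frequency_heatmap.tsv"),
                       sep = "\t", col.names = NA, quote = FALSE)
  }
  for (s in names(report$k_scans)) {
    write_k_scan(report$k_scans[[s]],
                 file.path(dir, paste0("kscan_", gsub("[^A-Za-z0-9]+", "_", s), ".tsv")))
  }
  summary_json <- list(
    counts = as.list(report$counts),
    n_clusters = report$n_clusters,
    seeds = report$seeds,
    strata = report$strata
  )
  writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA),
             file.path(dir, "report.json"))
  invisible(dir)
}
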