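#' Load an SDoH topic-label dictionary
#'
#' Reads a JSON file mapping label name to a keyword array. With no
#' argument, loads the packaged dictionary of 11 SDoH labels (mental
#' health, family, risk of death, social support, insurance/income, ...)
#' whose keyword sets drive both the labeling heuristic and the planted
#' synthetic topics. Keywords are lowercased and deduplicated; every
#' keyword must be a single alphabetic token.
#'
#' @param path Path to a JSON dictionary; default the packaged fixture.
#' @return A named list of character keyword sets with attribute
#'   `"provenance"` (`"packaged"` or the file path).
#' @export
load_label_dictionary <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "sdoh_labels.json", package = "sdohtopics")
  }
  dict <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(dict) == 0L) stop("label dictionary is empty")
  if (anyDuplicated(names(dict))) stop("duplicate label names in dictionary")
  dict <- lapply(dict, function(kw) unique(tolower(as.character(kw))))
  if (any(lengths(dict) == 0L)) stop("every label needs at least one keyword")
  bad <- unlist(dict)[!grepl("^[a-z]+$", unlist(dict))]
  if (length(bad)) stop("keywords must be lowercase single tokens: ",
                        paste(bad, collapse = ", "))
  attr(dict, "provenance") <- if (packaged) "packaged" else path
  dict
}

#' Expand a label dictionary with embedding nearest neighbors
#'
#' For each label, the `n_neighbors` words most cosine-similar to each of
#' its keywords (in the supplied word-embedding table) are added to the
#' label's keyword set. The manual-relevance review applied in interactive
#' use is replaced here by explicit `allow` / `deny` lists. The input
#' dictionary is not modified.
#'
#' @param dictionary A dictionary from [load_label_dictionary()].
#' @param embeddings Numeric matrix of word vectors, one row per word, with
#'   rownames.
#' @param n_neighbors Neighbors per keyword; 0 returns the input unchanged.
#' @param allow Optional character vector: if given, only these candidate
#'   words may be added.
#' @param deny Optional character vector of words that must not be added.
#' @return The expanded dictionary (provenance `"expanded"`).
#' @export
expand_dictionary <- function(dictionary, embeddings, n_neighbors = 20L,
                              allow = NULL, deny = NULL) {
  if (n_neighbors == 0L) return(dictionary)
  vocab <- rownames(embeddings)
  norms <- sqrt(rowSums(embeddings^2))
  out <- lapply(names(dictionary), function(lab) {
    kws <- dictionary[[lab]]
    added <- character(0)
    for (kw in kws) {
      if (!(kw %in% vocab)) {
        warning("keyword not in embeddings, skipped: ", kw)
        next
      }
      v <- embeddings[kw, ]
      sims <- as.vector(embeddings %*% v) / (norms * sqrt(sum(v^2)) + 1e-300)
      sims[vocab == kw] <- -Inf
      nn <- vocab[order(-sims, vocab)][seq_len(min(n_neighbors, length(vocab) - 1L))]
      added <- c(added, nn)
    }
    if (!is.null(allow)) added <- added[added %in% allow]
    if (!is.null(deny)) added <- added[!(added %in% deny)]
    unique(c(kws, added))
  })
  names(out) <- names(dictionary)
  attr(out, "provenance") <- "expanded"
  out
}

#' Assign an SDoH label to one topic cluster by intersection over union
#'
#' For each label h: overlap = |cluster ∩ keywords(h)|, union =
#' |cluster ∪ keywords(h)|, enrichment (IOU) = overlap / union. The label
#' with the maximum IOU is assigned, but only if its overlap is at least 2
#' words; otherwise no label is assigned. Exact IOU ties are broken by
#' lexicographic label name. The decision depends only on the cluster's
#' word *set*, never on the order of its top words.
#'
#' @param cluster_words Character vector of a topic's top words (>= 1).
#' @param dictionary A dictionary from [load_label_dictionary()].
#' @param min_overlap Minimum shared-word count for an assignment
#'   (default 2).
#' @return A one-row data frame: `label` (NA if unassigned), `iou`,
#'   `overlap`, `union`.
#' @examples
#' d <- load_label_dictionary()
#' assign_label(c("goal", "anxiety", "problem", "term", "depression",
#'                "mood", "therapy", "symptom", "long", "treatment"), d)
#' @export
assign_label <- function(cluster_words, dictionary, min_overlap = 2L) {
  cl <- unique(tolower(cluster_words))
  if (length(cl) == 0L) stop("cluster has no words")
  labs <- sort(names(dictionary))
  ov <- vapply(labs, function(h) length(intersect(cl, dictionary[[h]])), 0L)
  un <- vapply(labs, function(h) length(union(cl, dictionary[[h]])), 0L)
  iou <- ov / un
  best <- labs[order(-iou, labs)][1L]
  if (ov[best] >= min_overlap) {
    data.frame(label = best, iou = iou[[best]], overlap = ov[[best]],
               union = un[[best]], stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(label = NA_character_, iou = NA_real_, overlap = max(ov),
               union = NA_integer_, stringsAsFactors = FALSE, row.names = NULL)
  }
}

#' Label every cluster of a cluster inventory
#'
#' @param clusters Data frame from [topic_clusters()] (columns `category`,
#'   `run`, `topic`, list column `words`).
#' @param dictionary A dictionary from [load_label_dictionary()].
#' @param min_overlap Minimum overlap for assignment.
#' @return `clusters` with columns `label`, `iou`, `overlap` appended.
#' @export
label_clusters <- function(clusters, dictionary, min_overlap = 2L) {
  res <- lapply(clusters$words, assign_label, dictionary = dictionary,
                min_overlap = min_overlap)
  clusters$label <- vapply(res, function(r) r$label, "")
  clusters$iou <- vapply(res, function(r) r$iou, 0)
  clusters$overlap <- vapply(res, function(r) r$overlap, 0L)
  clusters
}

#' Pool labeled clusters from replicate runs into label proportions
#'
#' The proportion of each label is the number of clusters assigned that
#' label across all runs divided by the total number of clusters across
#' all runs; unassigned clusters are counted in an explicit `"unlabeled"`
#' bucket. Proportions sum to 1 and are invariant to run order.
#'
#' @param labels Character vector of per-cluster labels (NA = unassigned),
#'   pooled over runs of one category.
#' @param all_labels Label universe for the output (default: the labels
#'   observed); `"unlabeled"` is always appended.
#' @return Named numeric vector of proportions summing to 1.
#' @export
pool_runs <- function(labels, all_labels = NULL) {
  if (length(labels) == 0L) stop("no cluster assignments to pool")
  if (is.null(all_labels)) all_labels <- sort(unique(labels[!is.na(labels)]))
  lv <- ifelse(is.na(labels), "unlabeled", labels)
  counts <- table(factor(lv, levels = c(all_labels, "unlabeled")))
  p <- as.vector(counts) / length(labels)
  names(p) <- names(counts)
  p
}
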