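#' The ten ICD-10 disease chapters used for stratification
#'
#' Returns the packaged chapter table: chapter name plus the inclusive
#' 3-character code range (e.g., Neoplasms C00-D49). Ranges are compared
#' lexicographically on the 3-character category, which matches ICD-10
#' code ordering (letters before/after digits never mix within a
#' position except the O9A terminus, which lexicographic order also
#' handles since "A" sorts after "9").
#'
#' @return Data frame with columns `chapter`, `start`, `end`.
#' @export
icd10_chapters <- function() {
  path <- system.file("extdata", "icd10_chapters.csv", package = "sdohtopics")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Map an ICD-10 code to one of the ten disease chapters
#'
#' Uppercases the code, takes its 3-character category (letter + 2
#' alphanumerics), and returns the chapter whose range contains it, or
#' `NA` for codes outside all ten ranges. Malformed codes (no leading
#' letter) yield `NA` with a warning.
#'
#' @param code Character vector of ICD-10 codes (e.g., `"C50.9"`).
#' @param chapters Chapter table; default [icd10_chapters()].
#' @return Character vector of chapter names (NA where unmapped).
#' @examples
#' map_icd10_chapter(c("G35", "C50.9", "Z99"))
#' @export
map_icd10_chapter <- function(code, chapters = icd10_chapters()) {
  code <- toupper(trimws(code))
  cat3 <- substr(code, 1L, 3L)
  malformed <- !grepl("^[A-Z][0-9A-Z]{2}", cat3)
  if (any(malformed & nzchar(code))) {
    warning("malformed ICD-10 code(s): ",
            paste(unique(code[malformed & nzchar(code)]), collapse = ", "))
  }
  out <- rep(NA_character_, length(code))
  v <- icd3_value(cat3)
  for (r in seq_len(nrow(chapters))) {
    lo <- icd3_value(chapters$start[r])
    hi <- icd3_value(chapters$end[r])
    in_range <- !malformed & !is.na(v) & v >= lo & v <= hi
    out[in_range & is.na(out)] <- chapters$chapter[r]
  }
  out
}

# Locale-independent ordinal of a 3-character ICD-10 category: each
# position ranks 0-9 below A-Z, matching ICD-10 code order (incl. O9A).
icd3_value <- function(cat3) {
  alphabet <- c(0:9, LETTERS)
  vapply(cat3, function(s) {
    if (is.na(s) || nchar(s) != 3L) return(NA_real_)
    idx <- match(strsplit(s, "")[[1]], alphabet)
    if (anyNA(idx)) return(NA_real_)
    sum((idx - 1) * 36^(2:0))
  }, 0, USE.NAMES = FALSE)
}

#' Per-category topic-label proportion matrix
#'
#' Builds the category-by-label proportion matrix from a labeled cluster
#' inventory: each row is [pool_runs()] applied to one category's pooled
#' clusters, so rows sum to 1 (including the `"unlabeled"` bucket).
#'
#' @param labeled Data frame from [label_clusters()] (needs `category`
#'   and `label`).
#' @param all_labels Label universe for the columns; default the packaged
#'   dictionary's label names.
#' @return Numeric matrix, rows = categories, columns = labels plus
#'   `"unlabeled"`; every row sums to 1.
#' @export
topic_proportions <- function(labeled, all_labels = names(load_label_dictionary())) {
  cats <- unique(labeled$category)
  if (length(cats) == 0L) stop("no categories")
  rows <- t(vapply(cats, function(cc) {
    pool_runs(labeled$label[labeled$category == cc], all_labels = all_labels)
  }, numeric(length(all_labels) + 1L)))
  rownames(rows) <- cats
  rows
}

#' Chi-squared word selection across note categories
#'
#' For every word and every category, computes the one-vs-rest chi-squared
#' statistic on token counts: observed counts are the word's tokens inside
#' versus outside the category, expected counts allocate the word's total
#' by the category's document share. Words are ranked per category by
#' ascending p-value (ties by descending statistic, then word), dropping
#' stopwords and words not overrepresented in the category; the top `n_top`
#' are reported. A per-category word-frequency proportion matrix
#' (word count / total tokens in category) is returned for heatmap use.
#'
#' @param dtm Sparse or dense document-term count matrix with column names.
#' @param categories Per-document category vector (>= 2 distinct values;
#'   no category may be empty).
#' @param stopwords Words excluded from the rankings; default
#'   [sdoh_stopwords()].
#' @param n_top Words reported per category (default 5).
#' @return A list: `top_words` (named list of per-category character
#'   vectors), `statistic` and `p_value` (category x word matrices), and
#'   `proportions` (category x word frequency matrix over the union of
#'   reported words).
#' @export
chi2_word_selection <- function(dtm, categories, stopwords = sdoh_stopwords(),
                                n_top = 5L) {
  X <- as.matrix(dtm)
  storage.mode(X) <- "double"
  categories <- as.character(categories)
  if (length(categories) != nrow(X)) stop("one category per document required")
  cats <- sort(unique(categories))
  if (length(cats) < 2L) stop("need at least 2 categories")
  if (any(table(factor(categories, levels = cats)) == 0L)) stop("empty category")
  words <- colnames(X)
  total_w <- colSums(X)
  stat <- matrix(0, length(cats), ncol(X), dimnames = list(cats, words))
  enriched <- stat > 0
  for (ci in seq_along(cats)) {
    in_c <- categories == cats[ci]
    o1 <- colSums(X[in_c, , drop = FALSE])
    o2 <- total_w - o1
    p <- mean(in_c)                       # category document share
    e1 <- total_w * p
    e2 <- total_w * (1 - p)
    s <- ifelse(total_w > 0, (o1 - e1)^2 / e1 + (o2 - e2)^2 / e2, 0)
    stat[ci, ] <- s
    enriched[ci, ] <- o1 > e1
  }
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  keep <- !(words %in% stopwords)
  top <- lapply(seq_along(cats), function(ci) {
    ok <- keep & enriched[ci, ] & total_w > 0
    cand <- words[ok]
    cand[order(pval[ci, ok], -stat[ci, ok], cand)][seq_len(min(n_top, length(cand)))]
  })
  names(top) <- cats
  sel <- sort(unique(unlist(top)))
  props <- matrix(0, length(cats), length(sel), dimnames = list(cats, sel))
  for (ci in seq_along(cats)) {
    in_c <- categories == cats[ci]
    tot <- sum(X[in_c, ])
    if (tot > 0) props[ci, ] <- colSums(X[in_c, sel, drop = FALSE]) / tot
  }
  list(top_words = top, statistic = stat, p_value = pval, proportions = props)
}
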