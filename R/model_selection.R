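#' Sliding-window NPMI coherence of a topic's top words
#'
#' Implements the sliding-window, one-set-segmentation coherence with an
#' indirect confirmation measure: virtual documents are all windows of
#' `window` consecutive tokens slid (step 1) over each tokenized document
#' (a document shorter than the window contributes a single window); word
#' and word-pair probabilities are the fraction of windows containing the
#' word(s); each top word w_i gets a context vector of normalized pointwise
#' mutual information values \eqn{\mathrm{NPMI}(w_i, w_j)} against every
#' top word; the score is the mean over i of the cosine similarity between
#' w_i's vector and the sum of all top words' vectors.
#'
#' NPMI of a pair that never co-occurs in any window is -1; the NPMI of a
#' word with itself is +1. A top word absent from every window is handled
#' with an epsilon probability (and a warning): its self-NPMI is 1 and its
#' cross terms are -1.
#'
#' @param top_words Character vector of a topic's top words.
#' @param corpus_tokens List of token vectors (the tokenized corpus the
#'   probabilities are estimated from).
#' @param window Sliding-window width in tokens; default 110.
#' @return Coherence score (a real, typically in `[0, 1]`).
#' @export
topic_coherence <- function(top_words, corpus_tokens, window = 110L) {
  if (window < 2L) stop("window must be >= 2")
  top_words <- unique(top_words)
  W <- length(top_words)
  cnt <- window_cooccurrence(top_words, corpus_tokens, window)
  npmi <- npmi_matrix(cnt$pair, cnt$n_windows, top_words)
  v_sum <- colSums(npmi)
  mean(vapply(seq_len(W), function(i) cosine_sim(npmi[i, ], v_sum), 0))
}

# Boolean window counts: for each word (and unordered word pair) of `words`,
# the number of windows containing it. Returns the symmetric pair-count
# matrix (diagonal = single-word counts) and the total number of windows.
window_cooccurrence <- function(words, corpus_tokens, window) {
  W <- length(words)
  pair <- matrix(0, W, W, dimnames = list(words, words))
  n_windows <- 0L
  for (tk in corpus_tokens) {
    L <- length(tk)
    if (L == 0L) next
    if (L <= window) {
      n_windows <- n_windows + 1L
      present <- words %in% tk
      pair <- pair + outer(present, present)
    } else {
      nw <- L - window + 1L
      n_windows <- n_windows + nw
      ind <- matrix(FALSE, nw, W)
      for (w in seq_len(W)) {
        b <- as.integer(tk == words[w])
        cs <- c(0L, cumsum(b))
        ind[, w] <- (cs[(window + 1L):(L + 1L)] - cs[1:nw]) > 0L
      }
      pair <- pair + crossprod(ind)
    }
  }
  list(pair = pair, n_windows = n_windows)
}

# NPMI context vectors from window counts; rows are the per-word vectors.
npmi_matrix <- function(pair, n_windows, words, eps = 1e-12) {
  W <- nrow(pair)
  singles <- diag(pair)
  if (any(singles == 0)) {
    warning("top word(s) absent from every window: ",
            paste(words[singles == 0], collapse = ", "))
  }
  p1 <- singles / n_windows
  npmi <- matrix(-1, W, W, dimnames = dimnames(pair))
  for (i in seq_len(W)) for (j in seq_len(W)) {
    pj <- pair[i, j] / n_windows
    if (pair[i, j] > 0) {
      pmi <- log((pj + eps) / (p1[i] * p1[j]))
      npmi[i, j] <- pmi / (-log(pj + eps))
    }
  }
  diag(npmi)[singles == 0] <- 1
  npmi
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Jaccard similarity of two word sets
#'
#' \eqn{|A \cap B| / |A \cup B|}. Duplicated entries are collapsed.
#'
#' @param a,b Character vectors (at least one nonempty).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) stop("both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Mean pairwise topic similarity of a model's top-word sets
#'
#' The redundancy score S: the arithmetic mean of [jaccard()] over all
#' unordered pairs of topics. Lower values indicate a less redundant
#' topic set.
#'
#' @param top_word_sets List of >= 2 character vectors, one per topic.
#' @return Mean pairwise Jaccard similarity in `[0, 1]`.
#' @export
topic_similarity <- function(top_word_sets) {
  K <- length(top_word_sets)
  if (K < 2L) stop("need at least 2 topics")
  sims <- c()
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    sims <- c(sims, jaccard(top_word_sets[[i]], top_word_sets[[j]]))
  }
  mean(sims)
}

#' Pick the topic number by the coherence/similarity rank-sum rule
#'
#' Each candidate K gets rank i by descending coherence C (1 = highest) and
#' rank j by ascending similarity S (1 = smallest); ties share the best
#' (smallest) rank (competition ranking). The K minimizing i + j wins;
#' a tie on i + j is broken by the smaller K.
#'
#' @param scan Data frame with columns `K`, `C`, `S` (one row per
#'   candidate), e.g., from [scan_k()].
#' @return The selected K (integer). The full ranked table is attached as
#'   attribute `"ranks"` (columns `K`, `C`, `S`, `i`, `j`, `rank_sum`,
#'   `selected`).
#' @export
select_k <- function(scan) {
  if (is.null(scan) || nrow(scan) == 0L) stop("empty K scan")
  i <- rank(-scan$C, ties.method = "min")
  j <- rank(scan$S, ties.method = "min")
  rs <- i + j
  best <- which(rs == min(rs))
  sel <- best[which.min(scan$K[best])]
  ranks <- data.frame(K = scan$K, C = scan$C, S = scan$S, i = i, j = j,
                      rank_sum = rs, selected = seq_len(nrow(scan)) == sel)
  structure(as.integer(scan$K[sel]), ranks = ranks)
}

#' Scan candidate topic numbers, scoring coherence and similarity
#'
#' Fits LDA for every K on the grid (optionally with several replicate
#' seeds per K, averaging C and S over replicates before ranking) and
#' returns the scan table consumed by [select_k()].
#'
#' @param x Document-term matrix or [build_dtm()] list.
#' @param corpus_tokens Tokenized corpus for the coherence windows.
#' @param k_grid Candidate topic numbers (the full-corpus convention is
#'   `10:50`; small corpora warrant smaller grids).
#' @param seeds Replicate seeds per K (default one replicate, seed 1).
#' @param n_top Top words per topic for both C and S (default 10).
#' @param window Coherence window width.
#' @param ... Passed to [lda_vb()].
#' @return Data frame with columns `K`, `C`, `S` plus attribute
#'   `"selected"` = [select_k()] result.
#' @export
scan_k <- function(x, corpus_tokens, k_grid, seeds = 1L, n_top = 10L,
                   window = 110L, ...) {
  if (length(k_grid) == 0L) stop("empty K grid")
  rows <- lapply(k_grid, function(K) {
    cs <- vapply(seeds, function(s) {
      fit <- lda_vb(x, K = K, seed = s, ...)
      tws <- lapply(seq_len(K), function(k) as.character(top_words(fit, k, n_top)))
      C <- mean(vapply(tws, topic_coherence, 0, corpus_tokens = corpus_tokens,
                       window = window))
      S <- if (K >= 2L) topic_similarity(tws) else 0
      c(C, S)
    }, c(0, 0))
    data.frame(K = K, C = mean(cs[1, ]), S = mean(cs[2, ]))
  })
  scan <- do.call(rbind, rows)
  sel <- select_k(scan)
  attr(scan, "selected") <- sel
  scan
}

#' Write a K-scan report as TSV
#'
#' Columns: K, C, S, i, j, rank sum, and the selected flag.
#'
#' @param scan Output of [scan_k()] (or any `K`/`C`/`S` table).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_k_scan <- function(scan, path) {
  ranks <- attr(select_k(scan), "ranks")
  utils::write.table(ranks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
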