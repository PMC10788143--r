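#' English stopword list
#'
#' Returns the packaged English stopword list used throughout the pipeline.
#' The list is shipped as a static file so results do not drift with
#' library versions; it includes the contraction fragments ("don", "t",
#' "ve", ...) that the alphabetic tokenizer produces from possessives and
#' negations.
#'
#' @return Character vector of lowercase stopwords.
#' @export
sdoh_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "sdohtopics")
  readLines(path, encoding = "UTF-8")
}

#' Tokenize raw note text
#'
#' Lowercases, collapses tab/newline/whitespace runs, strips every
#' non-alphabetic character, splits into tokens, and removes stopwords and
#' empty tokens. Tokens are maximal runs of ASCII letters; digits and
#' punctuation act as separators.
#'
#' @param text Character vector of raw note texts.
#' @param stopwords Lowercase stopword set; default [sdoh_stopwords()].
#' @return A list of character vectors, one per input text.
#' @examples
#' tokenize_text("The\tpatient\nis anxious.", stopwords = c("the", "is"))
#' @export
tokenize_text <- function(text, stopwords = sdoh_stopwords()) {
  txt <- tolower(text)
  txt <- gsub("[^a-z]+", " ", txt)
  toks <- strsplit(trimws(txt), " +")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk[!(tk %in% stopwords)]
  })
}

#' Build a document-term matrix from token lists
#'
#' The vocabulary is the lexicographically sorted set of distinct tokens;
#' entry (d, w) counts occurrences of word w in document d. Construction is
#' deterministic: the same corpus always yields byte-identical matrices.
#'
#' @param token_lists List of token character vectors (e.g., from
#'   [tokenize_text()]).
#' @param doc_ids Optional row names (note ids); defaults to `doc1..docD`.
#' @return A list with elements `dtm` (a sparse `dgCMatrix` of counts,
#'   rows = documents) and `vocab` (character vector; column `j` of `dtm`
#'   is word `vocab[j]`).
#' @export
build_dtm <- function(token_lists, doc_ids = NULL) {
  if (length(token_lists) == 0L || all(lengths(token_lists) == 0L)) {
    stop("empty corpus: no documents with tokens")
  }
  vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  D <- length(token_lists)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_len(D)) {
    tk <- token_lists[[d]]
    if (length(tk) == 0L) next
    cnt <- table(tk)
    ii <- c(ii, rep.int(d, length(cnt)))
    jj <- c(jj, match(names(cnt), vocab))
    xx <- c(xx, as.integer(cnt))
  }
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(D))
  dtm <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(D, length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
  list(dtm = dtm, vocab = vocab)
}

#' Export a document-term matrix as MatrixMarket plus a vocabulary file
#'
#' Writes `<prefix>.mtx` (coordinate MatrixMarket) and `<prefix>.vocab.txt`
#' (one word per line; line number = 1-based column index).
#'
#' @param dtm Sparse document-term matrix.
#' @param vocab Character vocabulary aligned with the columns of `dtm`.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_dtm_mtx <- function(dtm, vocab, prefix) {
  stopifnot(ncol(dtm) == length(vocab))
  mtx <- paste0(prefix, ".mtx")
  vcb <- paste0(prefix, ".vocab.txt")
  Matrix::writeMM(methods::as(dtm, "CsparseMatrix"), mtx)
  writeLines(vocab, vcb)
  invisible(c(matrix = mtx, vocab = vcb))
}
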