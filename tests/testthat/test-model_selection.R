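toy_corpus_tokens <- function() {
  # 20 small documents with a planted co-occurring pair and a never
  # co-occurring pair
  set.seed(7)
  lapply(1:20, function(i) {
    base <- sample(c("filler", "noise", "pad", "etc"), 6, replace = TRUE)
    if (i %% 2 == 0) c(base, "alpha", "beta") else c(base, "delta")
  })
}

test_that("coherence agrees with brute-force window enumeration", {
  toks <- toy_corpus_tokens()
  for (tw in list(c("alpha", "beta"), c("alpha", "delta"),
                  c("alpha", "beta", "delta", "filler"))) {
    expect_equal(topic_coherence(tw, toks, window = 5),
                 naive_coherence(tw, toks, window = 5), tolerance = 1e-9)
  }
  # windows narrower than documents exercise the sliding path
  long <- list(rep(c("a", "b", "c", "d"), 10), rep(c("a", "x", "y"), 8))
  expect_equal(topic_coherence(c("a", "b", "y"), long, window = 4),
               naive_coherence(c("a", "b", "y"), long, window = 4),
               tolerance = 1e-9)
})

test_that("coherence honours its boundary conventions", {
  toks <- toy_corpus_tokens()
  # single top word: self-similarity 1
  expect_equal(topic_coherence("alpha", toks, window = 5), 1)
  # never co-occurring pair scores below a perfectly co-occurring one
  expect_lt(topic_coherence(c("alpha", "delta"), toks, window = 5),
            topic_coherence(c("alpha", "beta"), toks, window = 5))
  # invariant to top-word order
  expect_equal(topic_coherence(c("alpha", "beta", "delta"), toks, 5),
               topic_coherence(c("delta", "alpha", "beta"), toks, 5))
  # absent word handled with a warning
  expect_warning(topic_coherence(c("alpha", "zzz"), toks, window = 5), "absent")
})

test_that("jaccard matches set arithmetic including the printed worked example", {
  expect_equal(jaccard(letters[1:10], letters[1:10]), 1)
  expect_equal(jaccard(letters[1:5], letters[6:10]), 0)
  cluster1 <- c("goal", "anxiety", "problem", "term", "depression",
                "mood", "therapy", "symptom", "long", "treatment")
  mental <- load_label_dictionary()[["Mental health"]]
  expect_identical(intersect(cluster1, mental),
                   c("anxiety", "depression", "mood"))
  expect_equal(jaccard(cluster1, mental), 3 / 17)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("topic similarity is the mean pairwise jaccard", {
  expect_equal(topic_similarity(list(letters[1:3], letters[1:3], letters[1:3])), 1)
  expect_equal(topic_similarity(list(letters[1:3], letters[4:6], letters[7:9])), 0)
  # arithmetic-mean oracle on three unequal pairwise similarities
  sets <- list(c("a", "b", "c", "d"), c("a", "e", "f"), c("c", "g"))
  j <- c(jaccard(sets[[1]], sets[[2]]), jaccard(sets[[1]], sets[[3]]),
         jaccard(sets[[2]], sets[[3]]))
  expect_equal(topic_similarity(sets), mean(j))
  expect_error(topic_similarity(list(c("a"))), "at least 2")
})

test_that("select_k reproduces the worked rank-sum example and tie rules", {
  scan <- data.frame(K = c(10, 20, 30), C = c(0.5, 0.6, 0.4), S = c(0.3, 0.1, 0.2))
  sel <- select_k(scan)
  expect_identical(as.integer(sel), 20L)
  r <- attr(sel, "ranks")
  expect_identical(r$i, c(2L, 1L, 3L))
  expect_identical(r$j, c(3L, 1L, 2L))
  # ties on C and S: both candidates share ranks; smaller K wins
  tie <- data.frame(K = c(30, 10), C = c(0.5, 0.5), S = c(0.2, 0.2))
  expect_identical(as.integer(select_k(tie)), 10L)
  # single candidate
  expect_identical(as.integer(select_k(data.frame(K = 40, C = 0.1, S = 0.9))), 40L)
  expect_error(select_k(data.frame()), "empty")
})

test_that("select_k matches exhaustive rank enumeration on random tables", {
  set.seed(100)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    K <- sample(5:50, n)
    C <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    S <- round(runif(n), sample(c(1, 2, 6), 1))
    scan <- data.frame(K = K, C = C, S = S)
    expect_identical(as.integer(select_k(scan)), as.integer(naive_select_k(K, C, S)))
    # invariance to scan order
    perm <- sample(n)
    expect_identical(as.integer(select_k(scan[perm, ])), as.integer(select_k(scan)))
  }
})

test_that("scan_k fits the grid and reports the selected K", {
  rc <- recovery_corpus(seed = 3, n_docs_per_category = 15, doc_length_mean = 60)
  scan <- scan_k(rc$dtm, rc$tokens, k_grid = c(3, 5, 7), seeds = 1,
                 n_starts = 1, max_iter = 60)
  expect_identical(nrow(scan), 3L)
  expect_true(all(scan$S >= 0 & scan$S <= 1))
  expect_true(attr(scan, "selected") %in% scan$K)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_k_scan(scan, path)
  tab <- utils::read.delim(path)
  expect_identical(sum(tab$selected), 1L)
})
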