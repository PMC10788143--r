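# A tiny deterministic corpus reused across the engine tests.
toy_dtm <- function() {
  toks <- list(
    c("apple", "apple", "berry"),
    c("berry", "cherry", "cherry", "cherry"),
    c("apple", "cherry", "date"),
    c("date", "date", "berry", "apple")
  )
  build_dtm(toks)
}

test_that("K = 1 degenerates to the smoothed empirical word distribution", {
  m <- toy_dtm()
  fit <- lda_vb(m, K = 1, eta = 0.5, seed = 3, n_starts = 1)
  expect_equal(unname(fit$theta[, 1]), rep(1, 4))
  counts <- Matrix::colSums(m$dtm)
  expected <- (counts + 0.5) / sum(counts + 0.5)
  expect_equal(unname(fit$phi[1, ]), unname(as.vector(expected)), tolerance = 1e-8)
})

test_that("fitted simplexes are valid and the ELBO is monotone", {
  m <- toy_dtm()
  fit <- lda_vb(m, K = 3, seed = 11)
  expect_equal(unname(rowSums(fit$phi)), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(rowSums(fit$theta)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fit$phi >= 0) && all(fit$theta >= 0))
  el <- fit$elbo
  expect_true(all(diff(el) >= -1e-8 * abs(el[-length(el)])))
})

test_that("fits are reproducible for a fixed seed and error on bad K", {
  m <- toy_dtm()
  f1 <- lda_vb(m, K = 2, seed = 9)
  f2 <- lda_vb(m, K = 2, seed = 9)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$elbo, f2$elbo)
  expect_error(lda_vb(m, K = 0), "K must be")
  expect_warning(lda_vb(m, K = 6, seed = 1, n_starts = 1), "exceeds")
})

test_that("permuting topic indices leaves the variational bound unchanged", {
  m <- toy_dtm()
  fit <- lda_vb(m, K = 3, seed = 4)
  X <- as.matrix(m$dtm)
  storage.mode(X) <- "double"
  b0 <- sdohtopics:::lda_bound(X, fit$gamma, fit$lambda, fit$alpha, fit$eta)
  perm <- c(3, 1, 2)
  b1 <- sdohtopics:::lda_bound(X, fit$gamma[, perm], fit$lambda[perm, ],
                               fit$alpha, fit$eta)
  expect_equal(b0, b1, tolerance = 1e-10)
})

test_that("top words rank by weight with lexicographic tie-break", {
  fit <- structure(list(
    K = 1L,
    phi = matrix(c(0.2, 0.3, 0.2, 0.3), 1, 4,
                 dimnames = list("topic1", c("b", "d", "a", "c"))),
    vocab = c("b", "d", "a", "c")
  ), class = "lda_vb")
  expect_identical(as.character(top_words(fit, 1, 2)), c("c", "d"))
  expect_identical(as.character(top_words(fit, 1, 4)), c("c", "d", "a", "b"))
  expect_error(top_words(fit, 2, 2), "out of range")
})

test_that("replicate fits with distinct seeds yield the pooled cluster inventory", {
  m <- toy_dtm()
  fits <- run_replicates(m, K = 2, seeds = c(1, 2, 3), n_starts = 1, max_iter = 30)
  expect_length(fits, 3)
  cl <- topic_clusters(fits, category = "all", n_top = 3)
  expect_identical(nrow(cl), 6L)
  expect_true(all(lengths(cl$words) == 3))
  expect_error(run_replicates(m, K = 2, seeds = c(1, 1)), "distinct")
})

test_that("planted topic supports are recovered from synthetic corpora", {
  # smaller-scale recovery check; the full-scale study condition lives in
  # the acceptance suite
  rc <- recovery_corpus(seed = 21, n_docs_per_category = 30, doc_length_mean = 80)
  fit <- lda_vb(rc$dtm, K = 5, seed = 1)
  expect_gte(count_recovered(fit, rc$phi), 4L)
})

test_that("held-out topic quality matches an independent reference implementation", {
  # Fit this package's VB and scikit-learn's LDA on the same synthetic
  # corpus, then evaluate both topic sets with the same fold-in plug-in
  # perplexity; the reference is an oracle only.
  rc <- recovery_corpus(seed = 8, n_docs_per_category = 20, doc_length_mean = 60)
  prefix <- withr::local_tempfile()
  write_dtm_mtx(rc$dtm$dtm, rc$dtm$vocab, prefix)
  out_csv <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(
    "import scipy.io, numpy as np\nfrom sklearn.decomposition import LatentDirichletAllocation\nX = scipy.io.mmread(%s).tocsr()\nlda = LatentDirichletAllocation(n_components=5, doc_topic_prior=0.2, topic_word_prior=0.2, learning_method='batch', max_iter=100, random_state=0)\nlda.fit(X)\nphi = lda.components_ / lda.components_.sum(axis=1, keepdims=True)\nnp.savetxt(%s, phi, delimiter=',')\n",
    deparse(paste0(prefix, ".mtx")), deparse(out_csv))
  status <- suppressWarnings(system2("python", "-", input = script,
                                     stdout = FALSE, stderr = FALSE))
  skip_if(status != 0, "python/scikit-learn reference unavailable")
  ref_phi <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  colnames(ref_phi) <- rc$dtm$vocab
  fit <- lda_vb(rc$dtm, K = 5, seed = 1)
  p_own <- perplexity_lda(fit, rc$dtm)
  p_ref <- perplexity_lda(fit, rc$dtm, phi = ref_phi)
  expect_lt(abs(p_own - p_ref) / p_ref, 0.10)
})

test_that("models serialize to text and read back equivalent", {
  m <- toy_dtm()
  fit <- lda_vb(m, K = 2, seed = 5)
  dir <- withr::local_tempdir()
  write_topic_model(fit, dir)
  back <- read_topic_model(dir)
  expect_equal(back$phi, fit$phi, tolerance = 1e-12)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_identical(back$K, fit$K)
  expect_identical(as.character(top_words(back, 1, 3)),
                   as.character(top_words(fit, 1, 3)))
})
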