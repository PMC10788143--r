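#' Fit latent Dirichlet allocation by batch variational Bayes
#'
#' Mean-field variational inference for the LDA model. Each document d has a
#' topic mixture \eqn{\theta_d \sim \mathrm{Dirichlet}(\alpha)}; each topic k
#' a word distribution \eqn{\phi_k \sim \mathrm{Dirichlet}(\eta)}; each token
#' draws a topic from \eqn{\theta_d} and then a word from the drawn topic.
#' The posterior is approximated with the usual factorized family and fitted
#' by batch coordinate ascent on the evidence lower bound (ELBO): per-document
#' variational Dirichlet parameters gamma are iterated to convergence against
#' fixed topic parameters lambda, then lambda is updated from the pooled
#' sufficient statistics. The ELBO is non-decreasing across iterations up to
#' numerical tolerance.
#'
#' The batch estimator shares its fixed points with the online stochastic
#' variant commonly used on very large corpora, but is fully deterministic
#' for a fixed seed, which is what a reproducible desk-scale analysis needs.
#'
#' @param x A sparse or dense document-term count matrix (documents in rows),
#'   or the list returned by [build_dtm()].
#' @param K Number of topics (>= 1).
#' @param alpha Symmetric document-topic Dirichlet prior; default `1/K`.
#' @param eta Symmetric topic-word Dirichlet prior; default `1/K`.
#' @param seed Integer seed controlling initialization; default 1.
#' @param max_iter Maximum number of outer variational iterations.
#' @param tol Convergence threshold on the relative ELBO change.
#' @param n_starts Number of independently initialized restarts; the fit
#'   with the highest final ELBO is returned. The variational objective is
#'   non-convex and single starts can settle on merged or split topics;
#'   three restarts (the default) make recovery of well-separated topic
#'   structure reliable at desk scale. All restarts derive deterministically
#'   from `seed`.
#' @param verbose Print the ELBO trace while fitting.
#' @return An object of class `"lda_vb"` with components `phi` (K x V
#'   topic-word simplex), `theta` (D x K document-topic simplex), `lambda`
#'   and `gamma` (the variational Dirichlet parameters), `alpha`, `eta`,
#'   `K`, `seed`, `elbo` (trace of the best restart), `n_iter`,
#'   `converged`, `n_starts`, `restart_elbos`, `vocab`, `doc_ids`.
#' @examples
#' syn <- generate_corpus(corpus_config(n_docs_per_category = 10, seed = 1))
#' toks <- tokenize_text(syn$notes$text)
#' m <- build_dtm(toks)
#' fit <- lda_vb(m, K = 3, seed = 1, max_iter = 30)
#' top_words(fit, 1, 5)
#' @references Blei DM, Ng AY, Jordan MI (2003). Latent Dirichlet
#'   Allocation. JMLR 3:993-1022.
#' @export
lda_vb <- function(x, K, alpha = 1 / K, eta = 1 / K, seed = 1L,
                   max_iter = 200L, tol = 1e-4, n_starts = 3L,
                   verbose = FALSE) {
  if (is.list(x) && !is.null(x$dtm)) {
    vocab <- x$vocab
    x <- x$dtm
  } else {
    vocab <- colnames(x)
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  D <- nrow(X); V <- ncol(X)
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("K must be an integer >= 1")
  K <- as.integer(K)
  if (K > D) warning("K exceeds the number of documents; topics will be weakly identified")
  if (any(X < 0)) stop("count matrix must be nonnegative")
  if (is.null(vocab)) vocab <- paste0("w", seq_len(V))
  doc_ids <- rownames(X)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(D))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  fits <- lapply(sub_seeds, function(ss) {
    lda_vb_single(X, K, alpha, eta, ss, max_iter, tol, verbose)
  })
  finals <- vapply(fits, function(f) tail1(f$elbo), 0)
  best <- fits[[which.max(finals)]]

  phi <- best$lambda / rowSums(best$lambda)
  theta <- best$gamma / rowSums(best$gamma)
  dimnames(phi) <- list(paste0("topic", seq_len(K)), vocab)
  dimnames(theta) <- list(doc_ids, paste0("topic", seq_len(K)))
  structure(list(
    K = K, phi = phi, theta = theta, lambda = best$lambda, gamma = best$gamma,
    alpha = alpha, eta = eta, seed = as.integer(seed),
    elbo = best$elbo, n_iter = best$n_iter, converged = best$converged,
    n_starts = n_starts, restart_elbos = finals,
    vocab = vocab, doc_ids = doc_ids, n_tokens = sum(X)
  ), class = "lda_vb")
}

# One batch-VB run from one initialization.
lda_vb_single <- function(X, K, alpha, eta, seed, max_iter, tol, verbose) {
  D <- nrow(X); V <- ncol(X)
  n_total <- sum(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  # Topic-word init: small per-topic perturbations around the uniform
  # distribution; breaks symmetry without starving any word of mass.
  lambda <- matrix(stats::rgamma(K * V, shape = 100, rate = 100), K, V)
  gamma <- matrix(alpha + n_total / (D * K), D, K)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  elbo <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eb <- exp(dirichlet_elog(lambda))              # K x V
    es <- estep_gamma(X, gamma, eb, alpha)         # gamma + expElogtheta + phinorm
    gamma <- es$gamma
    sstats <- eb * (t(es$expElogtheta) %*% (X / es$phinorm))
    lambda <- eta + sstats
    bound <- lda_bound(X, gamma, lambda, alpha, eta)
    elbo <- c(elbo, bound)
    if (verbose) message(sprintf("iter %3d  elbo %.4f", it, bound))
    if (it > 1L) {
      rel <- abs(bound - elbo[it - 1L]) / abs(elbo[it - 1L])
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  list(lambda = lambda, gamma = gamma, elbo = elbo, n_iter = it,
       converged = converged)
}

# E[log X] for rows of independent Dirichlets parameterized by `a`.
dirichlet_elog <- function(a) digamma(a) - digamma(rowSums(a))

# Iterate the per-document gamma updates to convergence for fixed topics.
# X: D x V dense counts; eb = exp(E[log beta]) K x V.
estep_gamma <- function(X, gamma, eb, alpha, inner_max = 100L, inner_tol = 1e-5) {
  teb <- t(eb)
  for (i in seq_len(inner_max)) {
    et <- exp(dirichlet_elog(gamma))               # D x K
    phinorm <- et %*% eb + 1e-100                  # D x V
    gamma_new <- alpha + et * ((X / phinorm) %*% teb)
    delta <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    if (delta < inner_tol * mean(gamma)) break
  }
  et <- exp(dirichlet_elog(gamma))
  phinorm <- et %*% eb + 1e-100
  list(gamma = gamma, expElogtheta = et, phinorm = phinorm)
}

# Evidence lower bound for the current variational parameters (optimal
# token-level assignments are implicit in the log-sum-exp term).
lda_bound <- function(X, gamma, lambda, alpha, eta) {
  K <- nrow(lambda); V <- ncol(lambda); D <- nrow(X)
  elog_theta <- dirichlet_elog(gamma)
  elog_beta <- dirichlet_elog(lambda)
  phinorm <- exp(elog_theta) %*% exp(elog_beta) + 1e-100
  score <- sum(X * log(phinorm))
  # E[log p(theta | alpha)] - E[log q(theta | gamma)]
  score <- score + sum((alpha - gamma) * elog_theta) +
    sum(lgamma(gamma)) - D * K * lgamma(alpha) +
    D * lgamma(K * alpha) - sum(lgamma(rowSums(gamma)))
  # E[log p(beta | eta)] - E[log q(beta | lambda)]
  score + sum((eta - lambda) * elog_beta) +
    sum(lgamma(lambda)) - K * V * lgamma(eta) +
    K * lgamma(V * eta) - sum(lgamma(rowSums(lambda)))
}

#' @export
print.lda_vb <- function(x, ...) {
  cat(sprintf(
    "LDA (batch variational Bayes): %d topics, %d documents, %d words\n",
    x$K, nrow(x$theta), length(x$vocab)))
  cat(sprintf("alpha = %.4g, eta = %.4g, seed = %d\n", x$alpha, x$eta, x$seed))
  cat(sprintf("%d iterations, %sconverged, final ELBO %.2f\n",
              x$n_iter, if (x$converged) "" else "NOT ", tail1(x$elbo)))
  invisible(x)
}

tail1 <- function(v) if (length(v)) v[length(v)] else NA_real_

#' @export
summary.lda_vb <- function(object, n = 10L, ...) {
  tw <- lapply(seq_len(object$K), function(k) top_words(object, k, n))
  out <- list(model = object, top_words = tw, n = n)
  class(out) <- "summary.lda_vb"
  out
}

#' @export
print.summary.lda_vb <- function(x, ...) {
  print(x$model)
  cat("\nTop words per topic:\n")
  for (k in seq_along(x$top_words)) {
    cat(sprintf("  topic %2d: %s\n", k, paste(x$top_words[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.lda_vb <- function(object, ...) object$phi

#' @export
logLik.lda_vb <- function(object, ...) {
  structure(tail1(object$elbo), df = object$K * (length(object$vocab) - 1),
            nobs = object$n_tokens, class = "logLik")
}

#' @export
plot.lda_vb <- function(x, ...) {
  graphics::plot(seq_along(x$elbo), x$elbo, type = "b", pch = 16,
                 xlab = "iteration", ylab = "ELBO",
                 main = "Variational bound trace", ...)
  invisible(x)
}

#' Infer topic mixtures for new documents under a fitted model
#'
#' Folds new documents into a fitted model: the topic-word parameters stay
#' fixed and only the per-document variational Dirichlet parameters are
#' optimized.
#'
#' @param object A fitted `lda_vb` model.
#' @param newdata A document-term matrix over the same vocabulary (or a
#'   [build_dtm()] list, matched by word).
#' @param ... Unused.
#' @return A D x K matrix of document-topic proportions.
#' @export
predict.lda_vb <- function(object, newdata, ...) {
  X <- align_dtm(newdata, object$vocab)
  eb <- exp(dirichlet_elog(object$lambda))
  gamma <- matrix(object$alpha + sum(X) / (nrow(X) * object$K), nrow(X), object$K)
  es <- estep_gamma(X, gamma, eb, object$alpha)
  th <- es$gamma / rowSums(es$gamma)
  colnames(th) <- paste0("topic", seq_len(object$K))
  th
}

align_dtm <- function(newdata, vocab) {
  if (is.list(newdata) && !is.null(newdata$dtm)) {
    X <- as.matrix(newdata$dtm)
    colnames(X) <- newdata$vocab
  } else X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X)) && !identical(colnames(X), vocab)) {
    out <- matrix(0, nrow(X), length(vocab), dimnames = list(rownames(X), vocab))
    common <- intersect(colnames(X), vocab)
    out[, common] <- X[, common, drop = FALSE]
    X <- out
  }
  X
}

#' Plug-in perplexity of a corpus under a fitted model
#'
#' Folds the documents in (see [predict.lda_vb()]) and evaluates
#' \eqn{\exp(-\sum_{dw} n_{dw} \log(\theta_d^\top \phi_{\cdot w}) / N)}
#' with the point estimates of the simplexes. The same evaluation applied
#' to two different fitted topic sets gives a like-for-like comparison.
#'
#' @param model A fitted `lda_vb` model (or any list with `phi` rows
#'   summing to 1 plus `lambda`, `alpha`, `vocab`).
#' @param x A document-term matrix or [build_dtm()] list.
#' @param phi Optional replacement K x V topic-word matrix to evaluate with
#'   (e.g., topics from an external fit); defaults to `model$phi`.
#' @return Perplexity (positive scalar; lower is better).
#' @export
perplexity_lda <- function(model, x, phi = NULL) {
  X <- align_dtm(x, model$vocab)
  if (is.null(phi)) phi <- model$phi
  theta <- fold_in_theta(X, phi, model$alpha)
  p <- theta %*% phi
  ll <- sum(X * log(p + 1e-100))
  exp(-ll / sum(X))
}

# Fold-in e-step against an explicit point-estimate phi (works for topics
# from any implementation, not just this one).
fold_in_theta <- function(X, phi, alpha, inner_max = 200L, inner_tol = 1e-6) {
  eb <- pmax(phi, 1e-100)
  K <- nrow(phi)
  gamma <- matrix(alpha + sum(X) / (nrow(X) * K), nrow(X), K)
  es <- estep_gamma(X, gamma, eb, alpha, inner_max = inner_max, inner_tol = inner_tol)
  es$gamma / rowSums(es$gamma)
}

#' Top-ranked words of one topic
#'
#' Returns the `n` vocabulary words with the highest topic-word probability
#' for a topic, in descending weight order; exact weight ties are broken
#' lexicographically.
#'
#' @param model A fitted `lda_vb` model.
#' @param topic Topic index in `1..K`.
#' @param n Number of words (default 10, the convention used throughout the
#'   labeling pipeline).
#' @return Character vector of words with a `"weights"` attribute.
#' @export
top_words <- function(model, topic, n = 10L) {
  if (topic < 1L || topic > model$K) stop("topic index out of range")
  w <- model$phi[topic, ]
  n <- min(n, length(w))
  ord <- order(-w, model$vocab)[seq_len(n)]
  structure(model$vocab[ord], weights = unname(w[ord]))
}

#' Fit replicate LDA models with distinct seeds
#'
#' Runs one independently initialized fit per seed; downstream pooling
#' treats each replicate's topics as separate topic clusters.
#'
#' @param x Document-term matrix or [build_dtm()] list.
#' @param K Number of topics.
#' @param seeds Vector of distinct integer seeds (conventionally 5).
#' @param ... Passed to [lda_vb()].
#' @return List of `lda_vb` fits, one per seed.
#' @export
run_replicates <- function(x, K, seeds, ...) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s) lda_vb(x, K = K, seed = s, ...))
}

#' Render every topic of replicate fits as topic clusters
#'
#' @param models List of fitted `lda_vb` models (e.g., [run_replicates()]).
#' @param category Category string attached to each cluster.
#' @param n_top Top words per cluster.
#' @return Data frame with one row per (run, topic): `category`, `run`,
#'   `topic`, and `words` (list column of top-word vectors).
#' @export
topic_clusters <- function(models, category = "all", n_top = 10L) {
  rows <- list()
  for (r in seq_along(models)) {
    m <- models[[r]]
    for (k in seq_len(m$K)) {
      rows[[length(rows) + 1L]] <- list(
        category = category, run = r, topic = k,
        words = as.character(top_words(m, k, n_top))
      )
    }
  }
  data.frame(
    category = vapply(rows, `[[`, "", "category"),
    run      = vapply(rows, `[[`, 0L, "run"),
    topic    = vapply(rows, `[[`, 0L, "topic"),
    words    = I(lapply(rows, `[[`, "words")),
    stringsAsFactors = FALSE
  )
}

#' Serialize a fitted model to a directory
#'
#' Writes a JSON header (K, priors, seed, convergence state) plus `phi.tsv`
#' and `theta.tsv`, so fits are portable text.
#'
#' @param model A fitted `lda_vb` model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_topic_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(K = model$K, alpha = model$alpha, eta = model$eta,
                 seed = model$seed, n_iter = model$n_iter,
                 converged = model$converged, vocab = model$vocab,
                 doc_ids = model$doc_ids, elbo = model$elbo)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
             file.path(dir, "model.json"))
  utils::write.table(model$phi, file.path(dir, "phi.tsv"), sep = "\t",
                     col.names = NA, quote = FALSE)
  utils::write.table(model$theta, file.path(dir, "theta.tsv"), sep = "\t",
                     col.names = NA, quote = FALSE)
  invisible(dir)
}

#' Read a serialized model written by [write_topic_model()]
#' @param dir Directory containing `model.json`, `phi.tsv`, `theta.tsv`.
#' @return An `lda_vb` object (without the raw variational parameters).
#' @export
read_topic_model <- function(dir) {
  header <- jsonlite::fromJSON(file.path(dir, "model.json"))
  phi <- as.matrix(utils::read.table(file.path(dir, "phi.tsv"), sep = "\t",
                                     header = TRUE, row.names = 1, check.names = FALSE))
  theta <- as.matrix(utils::read.table(file.path(dir, "theta.tsv"), sep = "\t",
                                       header = TRUE, row.names = 1, check.names = FALSE))
  structure(list(
    K = header$K, phi = phi, theta = theta, lambda = NULL, gamma = NULL,
    alpha = header$alpha, eta = header$eta, seed = header$seed,
    elbo = header$elbo, n_iter = header$n_iter, converged = header$converged,
    vocab = header$vocab, doc_ids = header$doc_ids,
    n_tokens = NA_real_
  ), class = "lda_vb")
}
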