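test_that("the packaged dictionary has 11 valid SDoH labels", {
  d <- load_label_dictionary()
  expect_length(d, 11L)
  expect_identical(attr(d, "provenance"), "packaged")
  expect_setequal(d[["Mental health"]],
                  c("mental", "depression", "anxiety", "mood", "psychological",
                    "physical", "cognitive", "emotional", "mind", "psychiatric"))
  expect_true(all(lengths(d) >= 1))
  expect_true(all(grepl("^[a-z]+$", unlist(d))))
  # empty and duplicate-label files are rejected
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", empty)
  expect_error(load_label_dictionary(empty), "empty")
})

test_that("IOU labeling reproduces the brute-force assignment on a published cluster", {
  d <- load_label_dictionary()
  cluster1 <- c("goal", "anxiety", "problem", "term", "depression",
                "mood", "therapy", "symptom", "long", "treatment")
  # independent exhaustive IOU over all labels
  ious <- sapply(names(d), function(h) {
    length(intersect(cluster1, d[[h]])) / length(union(cluster1, d[[h]]))
  })
  ovs <- sapply(names(d), function(h) length(intersect(cluster1, d[[h]])))
  eligible <- ious[ovs >= 2]
  expect_identical(names(which.max(eligible)), "Mental health")

  a <- assign_label(cluster1, d)
  expect_identical(a$label, "Mental health")
  expect_equal(a$iou, 3 / 17)
  expect_identical(a$overlap, 3L)
  # beats the runner-up at 2/23
  expect_equal(unname(ious["Clinician/hospital/medication"]), 2 / 23)
})

test_that("labeling enforces the minimum-overlap floor and set semantics", {
  d <- load_label_dictionary()
  # shares exactly one word with a label -> unassigned
  a <- assign_label(c("mental", "xyzzy", "qwerty"), d)
  expect_true(is.na(a$label))
  # cluster equal to a keyword set -> that label at IOU 1
  a2 <- assign_label(d[["Insurance/income"]], d)
  expect_identical(a2$label, "Insurance/income")
  expect_equal(a2$iou, 1)
  # invariant to top-word order and case
  w <- c("family", "parent", "school", "child", "sister")
  expect_identical(assign_label(w, d), assign_label(rev(toupper(w)), d))
  # IOU bound: min/max cardinality ratio
  for (h in names(d)) {
    a3 <- assign_label(w, d)
    if (!is.na(a3$label)) {
      kw <- d[[a3$label]]
      bound <- min(length(w), length(kw)) / max(length(w), length(kw))
      expect_lte(a3$iou, bound)
    }
  }
})

test_that("deterministic lexicographic tie-break on equal IOU", {
  dict <- list("B label" = c("x", "y", "z"), "A label" = c("x", "y", "w"))
  a <- assign_label(c("x", "y"), dict)
  expect_identical(a$label, "A label")
})

test_that("embedding expansion adds nearest neighbours under allow/deny control", {
  d <- list("Mental health" = c("depression"), "Family" = c("family"))
  emb <- rbind(
    depression = c(1, 0, 0),
    depressed  = c(0.98, 0.1, 0),
    family     = c(0, 1, 0),
    families   = c(0, 0.99, 0.05),
    unrelated  = c(0, 0, 1)
  )
  # brute-force cosine: depressed is depression's nearest neighbour
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- apply(emb[rownames(emb) != "depression", ], 1, cosine, b = emb["depression", ])
  expect_identical(names(which.max(sims)), "depressed")

  e1 <- expand_dictionary(d, emb, n_neighbors = 1)
  expect_true("depressed" %in% e1[["Mental health"]])
  expect_true("families" %in% e1[["Family"]])
  # identity at zero neighbours; deny list blocks additions; original untouched
  expect_identical(expand_dictionary(d, emb, n_neighbors = 0), d)
  e2 <- expand_dictionary(d, emb, n_neighbors = 1, deny = "depressed")
  expect_false("depressed" %in% e2[["Mental health"]])
  expect_identical(d[["Mental health"]], "depression")
  expect_warning(expand_dictionary(list(A = "absent"), emb, 1), "skipped")
})

test_that("pooled label proportions count clusters and sum to one", {
  labels <- c(rep("Family", 10), rep(NA, 5), rep("Social support", 85))
  p <- pool_runs(labels)
  expect_equal(unname(p["Family"]), 0.10)
  expect_equal(unname(p["unlabeled"]), 0.05)
  expect_equal(sum(p), 1)
  # all unlabeled
  expect_equal(unname(pool_runs(rep(NA_character_, 4))["unlabeled"]), 1)
  # invariant to run order
  expect_equal(pool_runs(sample(labels)), p)
  expect_error(pool_runs(character(0)), "no cluster")
})

test_that("planted-topic round trip labels fitted matched topics correctly", {
  # plant the 11 SDoH topics, fit K = 11, and require >= 90% of the
  # fitted-and-matched topics to recover their planted label
  cfg <- corpus_config(n_docs_per_category = 25, topic_boost = NULL, seed = 17)
  syn <- generate_corpus(cfg)
  kept <- filter_notes(select_social_notes(syn$notes))
  m <- build_dtm(tokenize_text(kept$text), doc_ids = kept$note_id)
  fit <- lda_vb(m, K = 11, seed = 2)
  d <- load_label_dictionary()
  labs <- vapply(seq_len(11), function(k) {
    assign_label(as.character(top_words(fit, k, 10)), d)$label
  }, "")
  planted <- rownames(syn$ground_truth$phi)
  expect_gte(sum(labs %in% planted, na.rm = TRUE), 10)
  expect_gte(length(unique(stats::na.omit(labs))), 10)
})
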