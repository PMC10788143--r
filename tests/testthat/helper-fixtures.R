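# Shared fixtures and independent oracles, built in code.

# Minimal notes data frame; metadata defaults mark everything as social work.
make_notes <- function(texts,
                       note_type = "Progress Notes",
                       provider_type = "Clinical Social Worker",
                       department_name = "Social Work",
                       specialty = "",
                       encounter_type = "",
                       icd10 = NULL,
                       patient_id = NULL) {
  n <- length(texts)
  df <- data.frame(
    note_id = sprintf("n%03d", seq_len(n)),
    patient_id = if (is.null(patient_id)) sprintf("p%03d", seq_len(n)) else patient_id,
    text = texts,
    note_type = rep_len(note_type, n),
    encounter_type = rep_len(encounter_type, n),
    department_name = rep_len(department_name, n),
    specialty = rep_len(specialty, n),
    provider_type = rep_len(provider_type, n),
    year = rep(2020L, n),
    stringsAsFactors = FALSE
  )
  df$icd10_codes <- if (is.null(icd10)) replicate(n, character(0), simplify = FALSE) else icd10
  df
}

# Brute-force sliding-window NPMI/cosine coherence, written independently of
# the package implementation: enumerates every window as a character vector.
naive_coherence <- function(top_words, corpus_tokens, window) {
  top_words <- unique(top_words)
  windows <- list()
  for (tk in corpus_tokens) {
    L <- length(tk)
    if (L == 0) next
    if (L <= window) {
      windows[[length(windows) + 1]] <- tk
    } else {
      for (i in 1:(L - window + 1)) {
        windows[[length(windows) + 1]] <- tk[i:(i + window - 1)]
      }
    }
  }
  nw <- length(windows)
  p_one <- sapply(top_words, function(w) sum(sapply(windows, function(win) w %in% win)) / nw)
  W <- length(top_words)
  eps <- 1e-12
  npmi <- matrix(NA_real_, W, W)
  for (i in 1:W) for (j in 1:W) {
    joint <- sum(sapply(windows, function(win) top_words[i] %in% win && top_words[j] %in% win)) / nw
    if (joint == 0) {
      npmi[i, j] <- -1
    } else {
      npmi[i, j] <- log((joint + eps) / (p_one[i] * p_one[j])) / (-log(joint + eps))
    }
  }
  if (any(p_one == 0)) {
    for (i in which(p_one == 0)) npmi[i, i] <- 1
  }
  vs <- colSums(npmi)
  cosv <- sapply(1:W, function(i) {
    a <- npmi[i, ]
    sum(a * vs) / (sqrt(sum(a^2)) * sqrt(sum(vs^2)))
  })
  mean(cosv)
}

# Exhaustive rank-enumeration oracle for the K selection rule.
naive_select_k <- function(K, C, S) {
  n <- length(K)
  i <- sapply(seq_len(n), function(a) 1 + sum(C > C[a]))
  j <- sapply(seq_len(n), function(a) 1 + sum(S < S[a]))
  rs <- i + j
  cand <- which(rs == min(rs))
  K[cand[which.min(K[cand])]]
}

# Textbook chi-squared for a one-vs-rest token contingency table with
# expected counts from the category document share.
naive_chi2 <- function(count_in, count_out, share_in) {
  total <- count_in + count_out
  e <- c(total * share_in, total * (1 - share_in))
  o <- c(count_in, count_out)
  sum((o - e)^2 / e)
}

# Independent per-chapter membership rules for 3-character ICD-10 codes,
# written as explicit letter/number checks rather than range comparison.
naive_chapter <- function(code3) {
  letter <- substr(code3, 1, 1)
  num <- suppressWarnings(as.integer(substr(code3, 2, 3)))
  if (is.na(num)) return(NA_character_)
  if (letter == "G") return("Diseases of the nervous system")
  if (letter == "I") return("Diseases of the circulatory system")
  if (letter == "J") return("Diseases of the respiratory system")
  if (letter == "K" && num <= 95) return("Diseases of the digestive system")
  if (letter == "M") return("Diseases of the musculoskeletal system and connective tissue")
  if (letter == "N") return("Diseases of the genitourinary system")
  if (letter == "O") return("Pregnancy, childbirth and the puerperium")
  if (letter == "Q") return("Congenital malformations, deformations and chromosomal abnormalities")
  if (letter == "C") return("Neoplasms")
  if (letter == "D" && num <= 49) return("Neoplasms")
  if (letter == "D" && num >= 50 && num <= 89) {
    return("Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism")
  }
  NA_character_
}

# Greedy matching of fitted to planted topics by top-10 overlap; returns the
# number of planted supports recovered at >= `min_agree` of 10 words.
count_recovered <- function(fit, planted_phi, min_agree = 8, n_top = 10) {
  K <- nrow(planted_phi)
  vocab <- colnames(planted_phi)
  planted_top <- lapply(seq_len(K), function(k) {
    vocab[order(-planted_phi[k, ], vocab)][seq_len(n_top)]
  })
  fitted_top <- lapply(seq_len(fit$K), function(k) as.character(top_words(fit, k, n_top)))
  ov <- sapply(planted_top, function(p) {
    sapply(fitted_top, function(f) length(intersect(p, f)))
  })
  used <- integer(0)
  recovered <- 0L
  for (p in seq_len(K)) {
    avail <- ifelse(seq_len(fit$K) %in% used, -1L, ov[, p])
    best <- which.max(avail)
    used <- c(used, best)
    if (ov[best, p] >= min_agree) recovered <- recovered + 1L
  }
  recovered
}

# Small LDA-recovery corpus shared by several tests.
recovery_corpus <- function(seed, n_docs_per_category = 72, doc_length_mean = 100) {
  phi <- plant_disjoint_topics(5, 20)
  cfg <- corpus_config(
    n_docs_per_category = n_docs_per_category,
    doc_length_mean = doc_length_mean,
    topic_word = phi, topic_boost = NULL, seed = seed
  )
  syn <- generate_corpus(cfg)
  kept <- filter_notes(select_social_notes(syn$notes))
  toks <- tokenize_text(kept$text)
  m <- build_dtm(toks, doc_ids = kept$note_id)
  list(phi = phi, dtm = m, tokens = toks, ground_truth = syn$ground_truth)
}
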