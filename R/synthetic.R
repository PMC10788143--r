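#' Configuration for the synthetic social-work-note corpus generator
#'
#' The generator emulates the structure of a clinical social work note
#' repository: documents drawn from the LDA generative model with one
#' planted topic per SDoH dictionary label, metadata covering the four
#' analyzed note types and the ten ICD-10 disease chapters, and injected
#' contaminants (short notes, exact duplicates, notes with non-"social"
#' metadata) that exercise the preprocessing filters.
#'
#' Each of the 14 categories (4 note types + 10 chapters) receives exactly
#' `n_docs_per_category` base documents. Note-type documents carry no
#' ICD-10 code (so they enter only note-type strata); chapter documents
#' carry one representative code of their chapter and the minor note type
#' `"Letter"` (so they enter only chapter strata). This keeps per-stratum
#' document counts exact, which downstream bookkeeping tests rely on.
#'
#' @param n_docs_per_category Base documents per category (default 200).
#' @param K_true Planted topic count; default one per dictionary label.
#' @param alpha_true Document-topic Dirichlet concentration (default 0.1:
#'   most notes are dominated by one or two themes).
#' @param doc_length_mean Poisson mean token count per document (default
#'   60); lengths are truncated below at `min_tokens` so base documents
#'   always survive the 30-character filter.
#' @param min_tokens Minimum tokens per base document (default 8).
#' @param keyword_mass Probability mass a planted topic concentrates on
#'   its label's keyword set (default 0.9).
#' @param n_background Background (filler) vocabulary size (default 500),
#'   Zipf-weighted.
#' @param topic_boost Named list: category -> named numeric vector of
#'   per-label multipliers applied to `alpha_true` when drawing that
#'   category's topic mixtures. Defaults boost "Group session" in Group
#'   Notes and the telephone/online label in Telephone encounters, the
#'   two strongest category signatures in real social work notes.
#' @param short_rate,dup_rate,nonsocial_rate Contamination rates: injected
#'   contaminants per base document (each in `[0, 1]`, default 0.02).
#' @param dictionary Label dictionary whose keyword sets seed the planted
#'   topics; default the packaged one.
#' @param topic_word Optional explicit K x V topic-word matrix (rows sum
#'   to 1, columns named by word), overriding the planted SDoH topics;
#'   see [plant_disjoint_topics()].
#' @param seed Integer seed; identical configs + seeds give identical
#'   corpora.
#' @return A `generator_config` list.
#' @export
corpus_config <- function(n_docs_per_category = 200L,
                          K_true = NULL,
                          alpha_true = 0.1,
                          doc_length_mean = 60,
                          min_tokens = 8L,
                          keyword_mass = 0.9,
                          n_background = 500L,
                          topic_boost = list(
                            "Group Note" = c("Group session" = 6),
                            "Telephone encounters" = c("TelephoneEcounter/online communication" = 6)
                          ),
                          short_rate = 0.02,
                          dup_rate = 0.02,
                          nonsocial_rate = 0.02,
                          dictionary = NULL,
                          topic_word = NULL,
                          seed = 1L) {
  rates <- c(short_rate, dup_rate, nonsocial_rate)
  if (any(rates < 0 | rates > 1)) stop("contamination rates must be in [0, 1]")
  if (doc_length_mean <= 0) stop("doc_length_mean must be > 0")
  cfg <- list(
    n_docs_per_category = as.integer(n_docs_per_category),
    K_true = K_true, alpha_true = alpha_true,
    doc_length_mean = doc_length_mean, min_tokens = as.integer(min_tokens),
    keyword_mass = keyword_mass, n_background = as.integer(n_background),
    topic_boost = topic_boost,
    short_rate = short_rate, dup_rate = dup_rate,
    nonsocial_rate = nonsocial_rate,
    dictionary = dictionary, topic_word = topic_word,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

# Deterministic pseudo-word background vocabulary: open syllables composed
# pairwise/triple-wise, Zipf-weighted, with dictionary keywords excluded.
background_vocabulary <- function(n, exclude = character(0)) {
  syl <- c("ba", "ce", "di", "fo", "gu", "ha", "je", "ki", "lo", "mu",
           "na", "pe", "ri", "so", "tu", "va", "we", "xi", "yo", "zu",
           "bra", "cle", "dri", "flo", "gru")
  two <- as.vector(outer(syl, syl, paste0))
  three <- as.vector(outer(two, syl, paste0))
  words <- setdiff(c(two, three), exclude)
  if (length(words) < n) stop("background vocabulary exhausted")
  words[seq_len(n)]
}

zipf_weights <- function(n, s = 1) {
  w <- 1 / seq_len(n)^s
  w / sum(w)
}

#' Plant one topic-word distribution per SDoH dictionary label
#'
#' Each planted topic concentrates `keyword_mass` of its probability
#' uniformly on the label's keyword set and spreads the remainder
#' Zipf-weighted over the background vocabulary, so each topic's top words
#' are its own keywords and the topic round-trips through the IOU labeler.
#'
#' @param dictionary Label dictionary ([load_label_dictionary()]).
#' @param background Character vector of background words.
#' @param keyword_mass Mass on the keyword set (default 0.9).
#' @return K x V matrix (rows = labels, columns = vocabulary words, rows
#'   sum to 1).
#' @export
plant_sdoh_topics <- function(dictionary, background, keyword_mass = 0.9) {
  vocab <- sort(unique(c(unlist(dictionary), background)))
  K <- length(dictionary)
  phi <- matrix(0, K, length(vocab), dimnames = list(names(dictionary), vocab))
  bg_w <- zipf_weights(length(background)) * (1 - keyword_mass)
  for (k in seq_len(K)) {
    kws <- dictionary[[k]]
    phi[k, kws] <- keyword_mass / length(kws)
    phi[k, background] <- phi[k, background] + bg_w
  }
  phi
}

#' Plant K topics with disjoint Zipf-weighted word supports
#'
#' Builds a vocabulary of `K * support_size` synthetic words and gives
#' topic k geometric weights (ratio `decay`) over its own disjoint
#' `support_size`-word support, making each topic's top-word ranking
#' unambiguous. Used for topic-recovery experiments.
#'
#' @param K Number of topics.
#' @param support_size Words per topic support (default 20).
#' @param decay Geometric decay of within-support weights (default 0.85).
#' @return K x V topic-word matrix with named columns.
#' @export
plant_disjoint_topics <- function(K, support_size = 20L, decay = 0.85) {
  vocab <- background_vocabulary(K * support_size)
  phi <- matrix(0, K, length(vocab), dimnames = list(NULL, vocab))
  w <- decay^(seq_len(support_size) - 1L)
  w <- w / sum(w)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * support_size + 1L):(k * support_size)
    phi[k, cols] <- w
  }
  phi
}

note_type_schema <- function() {
  data.frame(
    note_type = c("Progress Notes", "Interdisciplinary",
                  "Telephone encounters", "Group Note"),
    stringsAsFactors = FALSE
  )
}

# One representative 3-character code per chapter so the chapter mapper is
# exercised on every chapter.
chapter_codes <- function() {
  c("Diseases of the nervous system" = "G35",
    "Diseases of the circulatory system" = "I10",
    "Diseases of the respiratory system" = "J45",
    "Diseases of the digestive system" = "K21",
    "Diseases of the musculoskeletal system and connective tissue" = "M54",
    "Diseases of the genitourinary system" = "N18",
    "Pregnancy, childbirth and the puerperium" = "O80",
    "Congenital malformations, deformations and chromosomal abnormalities" = "Q21",
    "Neoplasms" = "C50",
    "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism" = "D64")
}

#' Generate a synthetic social-work-note corpus with known ground truth
#'
#' Draws documents from the LDA generative model (topic mixture theta ~
#' Dirichlet(alpha_true) per document; each token draws a topic from theta
#' and a word from that topic's planted distribution), renders them as
#' space-joined text, attaches note-type / ICD-10 / patient metadata, and
#' injects the configured contaminants. Identical configs and seeds give
#' identical corpora.
#'
#' @param config A [corpus_config()].
#' @return A list: `notes` (notes data frame including contaminants),
#'   `ground_truth` (list with `phi` planted topic-word matrix, `theta`
#'   base-document mixtures, `category` per base document, `base_ids`,
#'   and `contamination` counts), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  if (!is.null(config$topic_word)) {
    phi <- config$topic_word
    if (any(abs(rowSums(phi) - 1) > 1e-8)) stop("topic_word rows must sum to 1")
    vocab <- colnames(phi)
    dict_labels <- rownames(phi)
  } else {
    dict <- config$dictionary
    if (is.null(dict)) dict <- load_label_dictionary()
    background <- background_vocabulary(config$n_background,
                                        exclude = unlist(dict))
    phi <- plant_sdoh_topics(dict, background, config$keyword_mass)
    vocab <- colnames(phi)
    dict_labels <- names(dict)
  }
  K <- nrow(phi)
  if (!is.null(config$K_true) && config$K_true != K) {
    stop("K_true does not match the planted topic matrix")
  }

  categories <- c(note_type_schema()$note_type, names(chapter_codes()))
  n_cat <- config$n_docs_per_category
  n_base <- n_cat * length(categories)

  theta <- matrix(0, n_base, K)
  texts <- character(n_base)
  cat_of <- rep(categories, each = n_cat)
  for (d in seq_len(n_base)) {
    a <- rep(config$alpha_true, K)
    boost <- config$topic_boost[[cat_of[d]]]
    if (!is.null(boost) && !is.null(dict_labels)) {
      hit <- match(names(boost), dict_labels)
      a[hit[!is.na(hit)]] <- a[hit[!is.na(hit)]] * boost[!is.na(hit)]
    }
    th <- stats::rgamma(K, shape = a)
    while (sum(th) == 0) th <- stats::rgamma(K, shape = a)
    th <- th / sum(th)
    theta[d, ] <- th
    len <- max(config$min_tokens, stats::rpois(1, config$doc_length_mean))
    z <- sample.int(K, len, replace = TRUE, prob = th)
    words <- character(len)
    for (k in unique(z)) {
      idx <- which(z == k)
      words[idx] <- vocab[sample.int(length(vocab), length(idx),
                                     replace = TRUE, prob = phi[k, ])]
    }
    texts[d] <- paste(words, collapse = " ")
  }
  # extremely unlikely base-text collisions would distort the duplicate
  # bookkeeping; disambiguate deterministically
  while (anyDuplicated(texts)) {
    i <- which(duplicated(texts))[1L]
    texts[i] <- paste(texts[i], vocab[sample.int(length(vocab), 1)])
  }

  is_type_cat <- cat_of %in% note_type_schema()$note_type
  codes <- chapter_codes()
  notes <- data.frame(
    note_id = sprintf("note%05d", seq_len(n_base)),
    patient_id = "",
    text = texts,
    note_type = ifelse(is_type_cat, cat_of, "Letter"),
    encounter_type = "Office Visit",
    department_name = "Social Work",
    specialty = "Social Work Services",
    provider_type = "Clinical Social Worker",
    year = sample(2012:2021, n_base, replace = TRUE),
    stringsAsFactors = FALSE
  )
  notes$icd10_codes <- lapply(seq_len(n_base), function(d) {
    if (is_type_cat[d]) character(0) else unname(codes[cat_of[d]])
  })

  # patients: sizes drawn so the 1 / 2-5 / >5 notes-per-patient strata are
  # all populated
  sizes <- 1L + stats::rpois(n_base, 2)
  sizes <- sizes[cumsum(sizes) <= n_base]
  if (sum(sizes) < n_base) sizes <- c(sizes, n_base - sum(sizes))
  notes$patient_id <- sprintf("pt%05d", rep(seq_along(sizes), times = sizes))

  # contaminants (appended after the base corpus)
  n_short <- as.integer(round(config$short_rate * n_base))
  n_dup <- as.integer(round(config$dup_rate * n_base))
  n_nonsocial <- as.integer(round(config$nonsocial_rate * n_base))
  extra <- list()
  if (n_short > 0) {
    short_texts <- vapply(seq_len(n_short), function(i) {
      paste(vocab[sample.int(length(vocab), 2)], collapse = " ")
    }, "")
    short_texts <- vapply(short_texts, function(s) substr(s, 1, 29), "")
    extra$short <- contaminant_rows(short_texts, "short", n_base, 0L)
  }
  if (n_dup > 0) {
    src <- sample.int(n_base, n_dup, replace = FALSE)
    extra$dup <- contaminant_rows(texts[src], "dup", n_base, n_short)
  }
  if (n_nonsocial > 0) {
    ns_idx <- sample.int(n_base, n_nonsocial, replace = FALSE)
    rows <- contaminant_rows(paste(texts[ns_idx], "x"), "nonsocial", n_base,
                             n_short + n_dup)
    rows$encounter_type <- "Office Visit"
    rows$department_name <- "Cardiology"
    rows$specialty <- "Cardiology"
    rows$provider_type <- "MD"
    extra$nonsocial <- rows
  }
  if (length(extra)) notes <- rbind(notes, do.call(rbind, unname(extra)))

  list(
    notes = notes,
    ground_truth = list(
      phi = phi,
      theta = theta,
      category = cat_of,
      base_ids = sprintf("note%05d", seq_len(n_base)),
      contamination = c(short = n_short, duplicate = n_dup,
                        nonsocial = n_nonsocial)
    ),
    config = config
  )
}

contaminant_rows <- function(texts, tag, n_base, offset) {
  n <- length(texts)
  df <- data.frame(
    note_id = sprintf("%s%05d", tag, seq_len(n) + offset + n_base),
    patient_id = sprintf("pt_extra%03d", seq_len(n) + offset),
    text = texts,
    note_type = "Progress Notes",
    encounter_type = "Office Visit",
    department_name = "Social Work",
    specialty = "Social Work Services",
    provider_type = "Clinical Social Worker",
    year = 2020L,
    stringsAsFactors = FALSE
  )
  df$icd10_codes <- replicate(n, character(0), simplify = FALSE)
  df
}
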