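# Reproducible synthetic corpora for character-level medical-style NER.
#
# The generator emulates the two phenomena that make boundary and category
# decisions hard in real clinical text: segmentation traps (a lexicon word
# whose strict prefix is itself a lexicon word, so a matcher fires on both)
# and category-ambiguous surface forms (one word carrying either of two
# categories, disambiguated only by its sentence context). Sentences are
# carrier-character strings with lexicon words inserted as entities; each
# entity is flanked by category-specific context cue characters, which is
# what makes ambiguous forms learnable. Carrier and entity words draw on
# disjoint sub-alphabets so that no accidental lexicon word spans an entity
# boundary.

#' Configuration for the synthetic corpus generator
#'
#' @param n_train,n_dev,n_test split sizes (sentences).
#' @param char_vocab_size alphabet size (split between carrier and
#'   entity-forming characters).
#' @param n_categories number of entity categories.
#' @param lexicon_size number of lexicon words.
#' @param entity_density expected entities per sentence (Poisson mean).
#' @param ambiguity_rate fraction of lexicon words carrying two categories,
#'   disambiguated by templated context.
#' @param trap_rate expected fraction of lexicon words whose strict prefix is
#'   itself a lexicon word (each trap pair consumes two lexicon slots, so
#'   rates above 0.5 are infeasible).
#' @param min_len,max_len target sentence length range (characters).
#' @param alphabet optional character vector to draw symbols from; defaults
#'   to a synthetic ASCII alphabet, configurable to real CJK codepoints.
#' @param seed RNG seed; fixes the generated lexicon and corpus exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_train = 2000L, n_dev = 200L, n_test = 400L,
                         char_vocab_size = 60L, n_categories = 3L,
                         lexicon_size = 40L, entity_density = 1.5,
                         ambiguity_rate = 0.2, trap_rate = 0.2,
                         min_len = 8L, max_len = 24L, alphabet = NULL,
                         seed = 13L) {
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1,
            trap_rate >= 0, trap_rate <= 1,
            entity_density >= 0, n_categories >= 1,
            min_len >= 1, max_len >= min_len)
  if (is.null(alphabet)) alphabet <- c(letters, LETTERS, as.character(0:9))
  if (char_vocab_size > length(alphabet)) {
    stop("char_vocab_size exceeds alphabet size (", length(alphabet), ")")
  }
  alphabet <- alphabet[seq_len(char_vocab_size)]
  structure(list(n_train = n_train, n_dev = n_dev, n_test = n_test,
                 char_vocab_size = char_vocab_size,
                 n_categories = n_categories, lexicon_size = lexicon_size,
                 entity_density = entity_density,
                 ambiguity_rate = ambiguity_rate, trap_rate = trap_rate,
                 min_len = min_len, max_len = max_len,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "synth_config")
}

synth_categories <- function(cfg) paste0("cat", seq_len(cfg$n_categories))

# Alphabet split: first half carries filler and context cues, second half
# forms lexicon words. The first 2 carrier characters per category are its
# context cues.
synth_pools <- function(cfg) {
  half <- max(2L * cfg$n_categories + 2L, floor(cfg$char_vocab_size / 2))
  if (half + 4L > cfg$char_vocab_size) {
    stop("char_vocab_size too small for ", cfg$n_categories, " categories")
  }
  carrier <- cfg$alphabet[seq_len(half)]
  entity <- cfg$alphabet[(half + 1L):cfg$char_vocab_size]
  cues <- lapply(seq_len(cfg$n_categories), function(k) {
    carrier[c(2L * k - 1L, 2L * k)]
  })
  names(cues) <- synth_categories(cfg)
  filler <- carrier[-seq_len(2L * cfg$n_categories)]
  list(filler = filler, entity = entity, cues = cues)
}

#' Generate a synthetic lexicon
#'
#' Multi-character pseudo-words (length 2-6) partitioned over categories.
#' Trap pairs (a word together with one of its strict prefixes) are created
#' at `trap_rate`; a fraction `ambiguity_rate` of words carries a second
#' category, recorded in the `"ambiguous"` attribute (the written lexicon
#' file keeps the single primary category).
#'
#' @param cfg a [synth_config()].
#' @return a [lexicon()] with attributes `ambiguous` (data.frame `word`,
#'   `category2`) and `trap_pairs` (count).
#' @export
generate_lexicon <- function(cfg) {
  if (cfg$lexicon_size == 0) return(lexicon())
  if (cfg$lexicon_size < cfg$n_categories) {
    stop("lexicon_size must be >= n_categories")
  }
  pools <- synth_pools(cfg)
  if (length(pools$entity) < 4) stop("entity alphabet too small")
  set.seed(cfg$seed)
  n_pairs <- stats::rbinom(1L, cfg$lexicon_size, cfg$trap_rate)
  n_pairs <- min(n_pairs, floor(cfg$lexicon_size / 2))
  words <- character()
  add_unique <- function(len) {
    for (try in 1:200) {
      w <- paste(sample(pools$entity, len, replace = TRUE), collapse = "")
      if (!w %in% words) return(w)
    }
    stop("cannot generate enough distinct words: vocabulary too small")
  }
  for (p in seq_len(n_pairs)) {
    repeat {
      long <- add_unique(sample(4:6, 1L))
      pre <- substr(long, 1L, sample(2:(nchar(long) - 2L), 1L))
      if (!pre %in% words && pre != long) break
    }
    words <- c(words, long, pre)
  }
  while (length(words) < cfg$lexicon_size) {
    words <- c(words, add_unique(sample(2:6, 1L)))
  }
  words <- words[seq_len(cfg$lexicon_size)]
  cats <- synth_categories(cfg)
  category <- cats[rep_len(seq_along(cats), length(words))][
    sample.int(length(words))]
  freq <- sample(1:9, length(words), replace = TRUE)
  lex <- lexicon(words, freq, category)
  n_amb <- round(cfg$ambiguity_rate * length(words))
  amb <- data.frame(word = character(), category2 = character(),
                    stringsAsFactors = FALSE)
  if (n_amb > 0 && cfg$n_categories > 1) {
    amb_idx <- sample.int(length(words), n_amb)
    cat2 <- vapply(amb_idx, function(i) {
      sample(setdiff(cats, lex$category[i]), 1L)
    }, "")
    amb <- data.frame(word = lex$word[amb_idx], category2 = cat2,
                      stringsAsFactors = FALSE)
  }
  attr(lex, "ambiguous") <- amb
  attr(lex, "trap_pairs") <- count_trap_pairs(lex)
  lex
}

#' Count trap pairs in a lexicon
#'
#' A trap pair is a word having a strict prefix that is itself a lexicon
#' word (the counted unit is the longer word).
#'
#' @param lex a [lexicon()].
#' @return integer count.
#' @export
count_trap_pairs <- function(lex) {
  words <- lex$word
  sum(vapply(words, function(w) {
    nc <- nchar(w)
    nc > 1 && any(substring(w, 1L, seq_len(nc - 1L)) %in% words)
  }, TRUE))
}

# Build one sentence; returns labeled_sequence.
synth_sentence <- function(cfg, lex, pools, amb) {
  k <- stats::rpois(1L, cfg$entity_density)
  if (nrow(lex) == 0) k <- 0L
  target <- sample(cfg$min_len:cfg$max_len, 1L)
  ent_words <- if (k > 0) sample(lex$word, k, replace = TRUE) else character()
  ent_cats <- vapply(ent_words, function(w) {
    i <- match(w, lex$word)
    cat1 <- lex$category[i]
    j <- match(w, amb$word)
    if (!is.na(j) && stats::runif(1) < 0.5) amb$category2[j] else cat1
  }, "", USE.NAMES = FALSE)
  used <- sum(nchar(ent_words)) + 2L * k
  fill_total <- max(target - used, k + 1L)
  cuts <- sort(sample.int(fill_total - 1L, min(k, fill_total - 1L)))
  seg_len <- diff(c(0L, cuts, fill_total))
  while (length(seg_len) < k + 1L) seg_len <- c(seg_len, 1L)
  chars <- character(); labels <- character()
  emit_fill <- function(len) {
    chars <<- c(chars, sample(pools$filler, len, replace = TRUE))
    labels <<- c(labels, rep("O", len))
  }
  for (j in seq_len(k)) {
    emit_fill(seg_len[j])
    cue <- pools$cues[[ent_cats[j]]]
    wch <- strsplit(ent_words[j], "")[[1]]
    chars <- c(chars, cue[1], wch, cue[2])
    labels <- c(labels, "O", paste0("B-", ent_cats[j]),
                rep(paste0("I-", ent_cats[j]), length(wch) - 1L), "O")
  }
  emit_fill(seg_len[k + 1L])
  labeled_sequence(chars, labels)
}

#' Generate a synthetic corpus
#'
#' Draws `n_train + n_dev + n_test` independent sentences under the template
#' described in the package vignette and assigns them to disjoint splits.
#' BIO labels mark exactly the inserted entity spans.
#'
#' @param cfg a [synth_config()].
#' @param lex lexicon from [generate_lexicon()] (its `ambiguous` attribute
#'   drives context-dependent categories).
#' @param out_dir optional directory: writes `train/dev/test.bio`,
#'   `train/dev/test.jsonl`, `lexicon.txt` and a `manifest.json` recording
#'   the configuration and seed.
#' @return list with `train`, `dev`, `test` (lists of [labeled_sequence()])
#'   and `lexicon`.
#' @export
generate_corpus <- function(cfg, lex, out_dir = NULL) {
  if (cfg$entity_density > 0 && nrow(lex) == 0) {
    stop("entity_density > 0 requires a non-empty lexicon")
  }
  pools <- synth_pools(cfg)
  amb <- attr(lex, "ambiguous")
  if (is.null(amb)) amb <- data.frame(word = character(),
                                      category2 = character())
  set.seed(cfg$seed + 1L)
  total <- cfg$n_train + cfg$n_dev + cfg$n_test
  sentences <- vector("list", total)
  for (i in seq_len(total)) {
    sentences[[i]] <- synth_sentence(cfg, lex, pools, amb)
  }
  splits <- list(
    train = sentences[seq_len(cfg$n_train)],
    dev = sentences[cfg$n_train + seq_len(cfg$n_dev)],
    test = sentences[cfg$n_train + cfg$n_dev + seq_len(cfg$n_test)])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(splits)) {
      write_bio_corpus(splits[[nm]], file.path(out_dir, paste0(nm, ".bio")))
      write_span_corpus(splits[[nm]], file.path(out_dir, paste0(nm, ".jsonl")))
    }
    write_lexicon(lex, file.path(out_dir, "lexicon.txt"))
    manifest <- unclass(cfg)
    manifest$alphabet <- paste(cfg$alphabet, collapse = "")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  c(splits, list(lexicon = lex))
}

#' k-fold cross-validation splits
#'
#' Shuffles the corpus and partitions it into k folds whose sizes differ by
#' at most one; fold i serves as the validation set of pair i.
#'
#' @param corpus list of sentences.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the shuffle.
#' @return list of k lists, each with `train` and `validation`.
#' @export
kfold_split <- function(corpus, k, seed = 1L) {
  n <- length(corpus)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds corpus size (", n, ")")
  set.seed(seed)
  idx <- sample.int(n)
  fold_of <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    val <- idx[fold_of == f]
    list(train = corpus[setdiff(idx, val)], validation = corpus[val])
  })
}
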