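#' Construct a labeled character sequence
#'
#' A `labeled_sequence` is the unit of training and evaluation: an ordered
#' vector of single-character tokens with an aligned vector of BIO tags.
#' Valid tags are `"O"`, `"B-<category>"` and `"I-<category>"`; an I- tag must
#' continue a same-category B- or I- tag.
#'
#' @param chars character vector of single-character tokens.
#' @param labels character vector of BIO tags, same length as `chars`.
#' @param validate check the BIO scheme (default `TRUE`).
#' @return an object of class `labeled_sequence` with fields `chars`,
#'   `labels` and `n`.
#' @export
labeled_sequence <- function(chars, labels = rep("O", length(chars)),
                             validate = TRUE) {
  chars <- as.character(chars)
  labels <- as.character(labels)
  if (length(chars) != length(labels)) {
    stop("chars and labels must have equal length (", length(chars), " vs ",
         length(labels), ")")
  }
  if (validate) validate_bio(labels)
  structure(list(chars = chars, labels = labels, n = length(chars)),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat("<labeled_sequence> n =", x$n, "\n")
  cat(" ", paste(x$chars, collapse = ""), "\n")
  sp <- bio_to_spans(x$labels)
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      cat(sprintf("  [%d,%d) %-10s %s\n", sp$start[i], sp$end[i],
                  sp$category[i],
                  paste(x$chars[(sp$start[i] + 1):sp$end[i]], collapse = "")))
    }
  }
  invisible(x)
}

# Split a BIO tag into prefix and category; category is NA for "O".
split_tag <- function(tag) {
  if (tag == "O") return(list(prefix = "O", category = NA_character_))
  if (!grepl("^[BI]-.+$", tag)) stop("invalid BIO tag: '", tag, "'")
  list(prefix = substr(tag, 1, 1), category = substring(tag, 3))
}

#' Validate (or repair) a BIO tag vector
#'
#' Strict mode rejects malformed tags and I- tags that do not continue a
#' same-category run. Lenient mode (`repair = TRUE`) promotes such orphan
#' I- tags to B-, mirroring the scheme noise found in real corpora.
#'
#' @param labels character vector of tags.
#' @param repair repair orphan I- tags instead of failing.
#' @return the (possibly repaired) label vector, invisibly in strict mode.
#' @export
validate_bio <- function(labels, repair = FALSE) {
  out <- labels
  prev_cat <- NA_character_
  for (i in seq_along(labels)) {
    t <- split_tag(labels[i])
    if (t$prefix == "I") {
      if (is.na(prev_cat) || prev_cat != t$category) {
        if (repair) {
          out[i] <- paste0("B-", t$category)
        } else {
          stop("BIO scheme violation at position ", i, ": '", labels[i],
               "' does not continue a '", t$category, "' entity")
        }
      }
      prev_cat <- t$category
    } else if (t$prefix == "B") {
      prev_cat <- t$category
    } else {
      prev_cat <- NA_character_
    }
  }
  if (repair) out else invisible(labels)
}

#' Create an entity-span table
#'
#' Spans use 0-based, half-open `[start, end)` character coordinates.
#'
#' @param start,end integer vectors, `0 <= start < end`.
#' @param category character vector of entity categories.
#' @return a data.frame with columns `start`, `end`, `category`.
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         category = character()) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("spans must satisfy 0 <= start < end")
  }
  df
}

# TRUE when any two spans in the table overlap.
spans_overlap <- function(spans) {
  if (nrow(spans) < 2) return(FALSE)
  o <- order(spans$start, spans$end)
  s <- spans[o, ]
  any(s$start[-1] < s$end[-nrow(s)])
}

#' Convert entity spans to BIO labels
#'
#' @param n sequence length.
#' @param spans data.frame with `start`, `end` (0-based half-open) and
#'   `category`.
#' @return character vector of `n` BIO tags: the first character of each span
#'   is tagged `B-<category>`, the remainder `I-<category>`, all else `"O"`.
#' @export
spans_to_bio <- function(n, spans) {
  labels <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0) return(labels)
  if (any(spans$start < 0) || any(spans$end > n) ||
      any(spans$end <= spans$start)) {
    stop("span out of range for sequence of length ", n)
  }
  if (spans_overlap(spans)) stop("overlapping spans")
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L
    e <- spans$end[i]
    labels[s] <- paste0("B-", spans$category[i])
    if (e > s) labels[(s + 1L):e] <- paste0("I-", spans$category[i])
  }
  labels
}

#' Convert BIO labels to entity spans
#'
#' Maximal B-I runs become spans; this is the exact inverse of
#' [spans_to_bio()] on scheme-valid input.
#'
#' @param labels character vector of BIO tags.
#' @param repair repair orphan I- tags (lenient mode) before conversion.
#' @return data.frame of spans (`start`, `end`, `category`), 0-based
#'   half-open, ordered by `start`.
#' @export
bio_to_spans <- function(labels, repair = FALSE) {
  labels <- validate_bio(labels, repair = repair)
  if (repair) labels <- labels else labels <- as.character(labels)
  starts <- integer(); ends <- integer(); cats <- character()
  cur_start <- NA_integer_; cur_cat <- NA_character_
  flush <- function(i) {
    if (!is.na(cur_start)) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- i
      cats[[length(cats) + 1L]] <<- cur_cat
    }
  }
  for (i in seq_along(labels)) {
    t <- split_tag(labels[i])
    if (t$prefix == "B") {
      flush(i - 1L)
      cur_start <- i - 1L
      cur_cat <- t$category
    } else if (t$prefix == "O") {
      flush(i - 1L)
      cur_start <- NA_integer_
      cur_cat <- NA_character_
    }
    # I- continues the current run (validity guaranteed above)
  }
  flush(length(labels))
  entity_spans(starts, ends, cats)
}

#' Read a CoNLL-style two-column BIO corpus
#'
#' One token per line as `character<TAB or space>tag`; a blank line separates
#' sentences. UTF-8 throughout.
#'
#' @param path file path.
#' @param repair lenient mode: repair orphan I- tags instead of failing.
#' @return list of [labeled_sequence()] objects in file order.
#' @export
read_bio_corpus <- function(path, repair = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  chars <- character(); labels <- character()
  flush <- function() {
    if (length(chars)) {
      labs <- validate_bio(labels, repair = repair)
      if (!repair) labs <- labels
      out[[length(out) + 1L]] <<- labeled_sequence(chars, labs,
                                                   validate = TRUE)
    }
    chars <<- character(); labels <<- character()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) { flush(); next }
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(fields) != 2) {
      stop("malformed line ", ln, " in ", path, ": expected 2 columns, got ",
           length(fields))
    }
    chars[[length(chars) + 1L]] <- fields[1]
    labels[[length(labels) + 1L]] <- fields[2]
  }
  flush()
  out
}

#' Write a corpus in CoNLL-style two-column BIO format
#'
#' @param corpus list of [labeled_sequence()] objects.
#' @param path output file path.
#' @export
write_bio_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (seq in corpus) {
    writeLines(paste(seq$chars, seq$labels, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a JSON-lines span corpus
#'
#' One JSON object per line:
#' `{"text": str, "entities": [{"start": int, "end": int, "type": str}]}`.
#'
#' @param path file path.
#' @return list of [labeled_sequence()] objects (labels from the spans).
#' @export
read_span_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    chars <- strsplit(obj$text, "")[[1]]
    ents <- obj$entities
    spans <- if (is.null(ents) || length(ents) == 0 ||
                 (is.data.frame(ents) && nrow(ents) == 0)) {
      entity_spans()
    } else {
      entity_spans(ents$start, ents$end, ents$type)
    }
    labeled_sequence(chars, spans_to_bio(length(chars), spans))
  })
}

#' Write a corpus as JSON-lines span annotations
#'
#' @param corpus list of [labeled_sequence()] objects.
#' @param path output file path.
#' @export
write_span_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (seq in corpus) {
    sp <- bio_to_spans(seq$labels)
    ents <- if (nrow(sp) == 0) list() else {
      lapply(seq_len(nrow(sp)), function(i) {
        list(start = sp$start[i], end = sp$end[i], type = sp$category[i])
      })
    }
    writeLines(jsonlite::toJSON(
      list(text = paste(seq$chars, collapse = ""), entities = ents),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Construct a lexicon of domain words
#'
#' @param word character vector of distinct multi-character words.
#' @param frequency non-negative counts (default 1).
#' @param category optional category strings (NA allowed).
#' @return object of class `lexicon`: a data.frame with columns `word`,
#'   `frequency`, `category`.
#' @export
lexicon <- function(word = character(), frequency = rep(1, length(word)),
                    category = rep(NA_character_, length(word))) {
  word <- as.character(word)
  dup <- unique(word[duplicated(word)])
  if (length(dup)) stop("duplicate lexicon word(s): ",
                        paste(dup, collapse = ", "))
  frequency <- as.numeric(frequency)
  if (any(frequency < 0)) stop("lexicon frequencies must be >= 0")
  structure(data.frame(word = word, frequency = frequency,
                       category = as.character(category),
                       stringsAsFactors = FALSE),
            class = c("lexicon", "data.frame"))
}

#' Load a lexicon from a plain-text file
#'
#' One word per line, with optional TAB-separated frequency and category:
#' `word[<TAB>frequency[<TAB>category]]`. Missing frequency defaults to 1.
#'
#' @param path file path.
#' @return a [lexicon()] object.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(lexicon())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  word <- vapply(parts, `[[`, "", 1)
  freq <- vapply(parts, function(p) {
    if (length(p) >= 2 && nzchar(p[2])) as.numeric(p[2]) else 1
  }, 0)
  cat <- vapply(parts, function(p) {
    if (length(p) >= 3 && nzchar(p[3])) p[3] else NA_character_
  }, "")
  lexicon(word, freq, cat)
}

#' Write a lexicon to a plain-text file
#'
#' @param lex a [lexicon()] object.
#' @param path output file path.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(lex))) {
    fields <- c(lex$word[i], format(lex$frequency[i], scientific = FALSE))
    if (!is.na(lex$category[i])) fields <- c(fields, lex$category[i])
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
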