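# Entity-level evaluation: strict span matching (start, end, category all
# correct), micro-averaged precision/recall/F1 plus per-category breakdown.

rate <- function(num, den) if (den > 0) num / den else 0

counts_to_rates <- function(tp, fp, fn) {
  p <- rate(tp, tp + fp)
  r <- rate(tp, tp + fn)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(TP = tp, FP = fp, FN = fn, P = p, R = r, F1 = f1)
}

# Match predicted spans against gold spans of one sentence; each gold span
# can be consumed at most once (exact duplicates in pred count once as TP).
match_sentence <- function(gold, pred) {
  key <- function(df) if (nrow(df)) {
    paste(df$start, df$end, df$category)
  } else character()
  gk <- key(gold); pk <- key(pred)
  tp_cat <- character(); fp_cat <- character()
  avail <- gk
  for (i in seq_along(pk)) {
    hit <- match(pk[i], avail)
    if (!is.na(hit)) {
      avail <- avail[-hit]
      tp_cat[[length(tp_cat) + 1L]] <- pred$category[i]
    } else {
      fp_cat[[length(fp_cat) + 1L]] <- pred$category[i]
    }
  }
  fn_cat <- gold$category[gk %in% avail]
  list(tp = tp_cat, fp = fp_cat, fn = fn_cat)
}

#' Entity-level precision, recall and F1
#'
#' Strict exact-match evaluation: a predicted span is a true positive iff a
#' gold span with identical (start, end, category) exists in the same
#' sentence. Counts are summed over sentences (micro-averaging); a
#' per-category table is reported alongside. Zero denominators yield rate 0.
#'
#' @param gold,pred lists (one element per sentence) of span data.frames as
#'   returned by [bio_to_spans()], or [labeled_sequence()] objects (spans are
#'   extracted from the labels).
#' @return object of class `entity_eval`: list with `overall` (TP, FP, FN,
#'   P, R, F1) and `by_category` (data.frame, one row per category plus
#'   macro-averaged rates as attributes).
#' @export
evaluate_entities <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("sentence-count mismatch: ", length(gold), " gold vs ",
         length(pred), " predicted")
  }
  as_spans <- function(x) {
    if (inherits(x, "labeled_sequence")) bio_to_spans(x$labels) else x
  }
  tp <- character(); fp <- character(); fn <- character()
  for (s in seq_along(gold)) {
    r <- match_sentence(as_spans(gold[[s]]), as_spans(pred[[s]]))
    tp <- c(tp, r$tp); fp <- c(fp, r$fp); fn <- c(fn, r$fn)
  }
  overall <- counts_to_rates(length(tp), length(fp), length(fn))
  cats <- sort(unique(c(tp, fp, fn)))
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    r <- counts_to_rates(sum(tp == cc), sum(fp == cc), sum(fn == cc))
    data.frame(category = cc, TP = r$TP, FP = r$FP, FN = r$FN,
               P = r$P, R = r$R, F1 = r$F1, stringsAsFactors = FALSE)
  }))
  if (is.null(by_cat)) {
    by_cat <- data.frame(category = character(), TP = integer(),
                         FP = integer(), FN = integer(), P = numeric(),
                         R = numeric(), F1 = numeric())
  }
  structure(list(overall = overall, by_category = by_cat),
            class = "entity_eval")
}

#' @export
print.entity_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf("entity-level micro: P=%.4f R=%.4f F1=%.4f (TP=%d FP=%d FN=%d)\n",
              o$P, o$R, o$F1, o$TP, o$FP, o$FN))
  if (nrow(x$by_category)) {
    print(x$by_category, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param ev an `entity_eval` object.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
eval_report_json <- function(ev, path = NULL) {
  by_cat <- ev$by_category
  rep <- list(overall = ev$overall,
              by_category = stats::setNames(
                lapply(seq_len(nrow(by_cat)), function(i) {
                  as.list(by_cat[i, c("TP", "FP", "FN", "P", "R", "F1")])
                }), by_cat$category))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
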