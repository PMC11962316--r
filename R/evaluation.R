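# Exact-string-match NER scoring: per-type and macro P/R/F1, plus the
# four-way error taxonomy (identification / type / boundary / missing).

mention_key <- function(m) paste0(m$etype, "\r", m$surface)

#' Match predicted against gold mentions of one sentence
#'
#' Greedy multiset matching on exact (surface string, type) equality: each
#' gold mention is consumed by at most one prediction, duplicates count
#' separately, and offsets are ignored so unanchored predictions still
#' match (set `strict_offsets = TRUE` to additionally require identical
#' offsets).
#'
#' @param pred,gold Lists of `ms_mention` belonging to one sentence.
#' @param strict_offsets Require offset equality as well.
#' @return List with `matched` (list of `list(pred, gold)` pairs),
#'   `unmatched_pred` and `unmatched_gold`.
#' @export
match_mentions <- function(pred, gold, strict_offsets = FALSE) {
  key <- function(m) {
    if (strict_offsets) paste0(mention_key(m), "\r", m$start, "\r", m$end)
    else mention_key(m)
  }
  gold_keys <- vapply(gold, key, character(1))
  taken <- rep(FALSE, length(gold))
  matched <- list()
  unmatched_pred <- list()
  for (p in pred) {
    hit <- which(!taken & gold_keys == key(p))
    if (length(hit)) {
      taken[hit[1]] <- TRUE
      matched[[length(matched) + 1L]] <- list(pred = p, gold = gold[[hit[1]]])
    } else {
      unmatched_pred[[length(unmatched_pred) + 1L]] <- p
    }
  }
  list(matched = matched, unmatched_pred = unmatched_pred,
       unmatched_gold = gold[!taken])
}

gold_by_sent <- function(gold_corpus) {
  sents <- corpus_sentences(gold_corpus)
  names(sents) <- vapply(sents, function(s) s$sent_id, character(1))
  sents
}

count_tp_fp_fn <- function(predictions, gold_sents, etype) {
  tp <- fp <- fn <- 0L
  for (id in names(gold_sents)) {
    g <- Filter(function(m) m$etype == etype, gold_sents[[id]]$mentions)
    p <- Filter(function(m) m$etype == etype, predictions[[id]] %||% list())
    res <- match_mentions(p, g)
    tp <- tp + length(res$matched)
    fp <- fp + length(res$unmatched_pred)
    fn <- fn + length(res$unmatched_gold)
  }
  c(tp = tp, fp = fp, fn = fn)
}

prf_from_counts <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F1 = f1)
}

#' Precision, recall and F1 for one entity type
#'
#' Aggregated over all sentences of the gold corpus under exact (surface,
#' type) matching. Conventions: P = 0 with no predictions, R = 0 with no
#' gold, F1 = 0 when P + R = 0.
#'
#' @param predictions Named list: `sent_id` to list of predicted
#'   `ms_mention`.
#' @param gold An `ms_corpus`.
#' @param etype One of [entity_types()].
#' @return Named numeric vector `(P, R, F1)`.
#' @export
prf <- function(predictions, gold, etype) {
  etype <- match.arg(etype, entity_types())
  cnt <- count_tp_fp_fn(predictions, gold_by_sent(gold), etype)
  prf_from_counts(cnt["tp"], cnt["fp"], cnt["fn"])
}

#' Macro F1
#'
#' Unweighted arithmetic mean of per-type F1 values — every entity class
#' counts equally regardless of its frequency.
#'
#' @param per_type_f1 Non-empty numeric vector (or list) of per-type F1
#'   values.
#' @return The mean.
#' @export
macro_f1 <- function(per_type_f1) {
  v <- unlist(per_type_f1)
  if (length(v) == 0) stop("macro_f1: empty per-type F1 mapping")
  mean(v)
}

overlaps_gold <- function(p, g, sentence_text = NULL) {
  # surface containment either way counts as a boundary relation; if both
  # are anchored, character-span overlap counts too
  if (grepl(p$surface, g$surface, fixed = TRUE) ||
      grepl(g$surface, p$surface, fixed = TRUE)) {
    return(TRUE)
  }
  if (mention_anchored(p) && mention_anchored(g)) {
    return(p$start < g$end && g$start < p$end)
  }
  FALSE
}

#' Classify unmatched predictions and gold mentions into error categories
#'
#' Precedence per unmatched prediction: exact surface match with a gold
#' mention of another type in the same sentence is a `type` error; else a
#' surface that is a substring/superstring of, or character-overlaps, some
#' gold surface is a `boundary` error; anything else is an `identification`
#' error (a non-entity labeled as an entity). Every gold mention with no
#' matching and no overlapping prediction is `missing`.
#'
#' @param predictions Named list: `sent_id` to predicted mentions.
#' @param gold An `ms_corpus`.
#' @return Tibble with columns `sent_id`, `category`, `pred_surface`,
#'   `pred_type`, `gold_surface`, `gold_type` (NA where not applicable).
#' @export
classify_errors <- function(predictions, gold) {
  gs <- gold_by_sent(gold)
  rows <- list()
  add <- function(sent_id, category, p = NULL, g = NULL) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      sent_id = sent_id, category = category,
      pred_surface = if (is.null(p)) NA_character_ else p$surface,
      pred_type = if (is.null(p)) NA_character_ else p$etype,
      gold_surface = if (is.null(g)) NA_character_ else g$surface,
      gold_type = if (is.null(g)) NA_character_ else g$etype)
  }
  for (id in names(gs)) {
    g_all <- gs[[id]]$mentions
    p_all <- predictions[[id]] %||% list()
    res <- match_mentions(p_all, g_all)
    overlapped <- rep(FALSE, length(res$unmatched_gold))
    for (p in res$unmatched_pred) {
      type_hit <- Filter(function(g)
        identical(g$surface, p$surface) && g$etype != p$etype, g_all)
      if (length(type_hit)) {
        add(id, "type", p, type_hit[[1]])
        next
      }
      bd <- vapply(g_all, function(g) overlaps_gold(p, g), logical(1))
      if (any(bd)) {
        add(id, "boundary", p, g_all[[which(bd)[1]]])
      } else {
        add(id, "identification", p)
      }
      # record which unmatched gold this prediction touches
      if (length(res$unmatched_gold)) {
        overlapped <- overlapped | vapply(res$unmatched_gold, function(g)
          overlaps_gold(p, g), logical(1))
      }
    }
    # type-error predictions also "touch" their gold counterpart
    for (p in res$unmatched_pred) {
      if (length(res$unmatched_gold)) {
        overlapped <- overlapped | vapply(res$unmatched_gold, function(g)
          identical(g$surface, p$surface) && g$etype != p$etype, logical(1))
      }
    }
    for (j in seq_along(res$unmatched_gold)) {
      if (!overlapped[j]) add(id, "missing", g = res$unmatched_gold[[j]])
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(sent_id = character(0), category = character(0),
                          pred_surface = character(0),
                          pred_type = character(0),
                          gold_surface = character(0),
                          gold_type = character(0)))
  }
  do.call(rbind, rows)
}

#' Evaluate predictions against a gold corpus
#'
#' Assembles per-type precision/recall/F1 with raw TP/FP/FN counts, the
#' macro F1 (unweighted mean over types present in gold or predictions;
#' types absent from both are excluded to avoid 0/0 artifacts on small
#' fixtures), micro-averaged P/R/F1, and the error-taxonomy records.
#'
#' @param predictions Named list: `sent_id` to list of predicted
#'   `ms_mention`. Every name must be a sentence of the gold corpus.
#' @param gold An `ms_corpus`.
#' @return Object of class `ms_eval`: list with `per_type` (tibble),
#'   `macro_f1`, `micro` (named vector), `errors` (tibble),
#'   `error_counts` (named integer vector).
#' @export
evaluate <- function(predictions, gold) {
  gs <- gold_by_sent(gold)
  unknown <- setdiff(names(predictions), names(gs))
  if (length(unknown)) {
    stop("evaluate: predictions reference unknown sent_id: ", unknown[1])
  }
  counts <- lapply(entity_types(), function(t)
    count_tp_fp_fn(predictions, gs, t))
  names(counts) <- entity_types()
  per_type <- do.call(rbind, lapply(entity_types(), function(t) {
    cnt <- counts[[t]]
    m <- prf_from_counts(cnt["tp"], cnt["fp"], cnt["fn"])
    tibble::tibble(etype = t, P = m[["P"]], R = m[["R"]], F1 = m[["F1"]],
                   TP = cnt[["tp"]], FP = cnt[["fp"]], FN = cnt[["fn"]])
  }))
  present <- per_type$TP + per_type$FP + per_type$FN > 0
  macro <- if (any(present)) macro_f1(per_type$F1[present]) else 0
  tot <- colSums(per_type[, c("TP", "FP", "FN")])
  micro <- prf_from_counts(tot["TP"], tot["FP"], tot["FN"])
  errors <- classify_errors(predictions, gold)
  cats <- c("identification", "type", "boundary", "missing")
  error_counts <- vapply(cats, function(cc)
    sum(errors$category == cc), integer(1))
  structure(
    list(per_type = per_type, macro_f1 = macro, micro = micro,
         errors = errors, error_counts = error_counts),
    class = "ms_eval"
  )
}

#' @export
print.ms_eval <- function(x, ...) {
  cat("Exact-match NER evaluation\n")
  df <- x$per_type
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-8s P=%6.2f%%  R=%6.2f%%  F1=%6.2f%%  (TP=%d FP=%d FN=%d)\n",
                df$etype[i], 100 * df$P[i], 100 * df$R[i], 100 * df$F1[i],
                df$TP[i], df$FP[i], df$FN[i]))
  }
  cat(sprintf("  macro F1 = %.2f%%   micro P/R/F1 = %.2f/%.2f/%.2f%%\n",
              100 * x$macro_f1, 100 * x$micro["P"], 100 * x$micro["R"],
              100 * x$micro["F1"]))
  cat("  errors:",
      paste(names(x$error_counts), x$error_counts, sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report An `ms_eval`.
#' @param path_prefix Files `<prefix>.csv` (per-type rows plus macro/micro)
#'   and `<prefix>.json` (full report) are written; error records go to
#'   `<prefix>_errors.jsonl`.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, path_prefix) {
  df <- report$per_type
  extra <- tibble::tibble(
    etype = c("macro", "micro"),
    P = c(NA, report$micro[["P"]]),
    R = c(NA, report$micro[["R"]]),
    F1 = c(report$macro_f1, report$micro[["F1"]]),
    TP = NA_integer_, FP = NA_integer_, FN = NA_integer_)
  csv <- paste0(path_prefix, ".csv")
  utils::write.csv(rbind(df, extra), csv, row.names = FALSE)
  js <- paste0(path_prefix, ".json")
  jsonlite::write_json(
    list(per_type = df, macro_f1 = report$macro_f1,
         micro = as.list(report$micro),
         error_counts = as.list(report$error_counts)),
    js, auto_unbox = TRUE, digits = NA)
  jl <- paste0(path_prefix, "_errors.jsonl")
  con <- file(jl, open = "w", encoding = "UTF-8")
  if (nrow(report$errors) > 0) {
    for (i in seq_len(nrow(report$errors))) {
      writeLines(jsonlite::toJSON(as.list(report$errors[i, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  close(con)
  invisible(c(csv, js, jl))
}

#' Write predictions as JSON Lines
#'
#' One line per sentence: `{"sent_id", "entities": [{"text", "type",
#' "start", "end"}]}`; unanchored mentions omit offsets.
#'
#' @param predictions Named list: `sent_id` to list of `ms_mention`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (id in names(predictions)) {
    rec <- list(sent_id = id,
                entities = lapply(predictions[[id]], mention_to_list))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path JSON-Lines file.
#' @return Named list: `sent_id` to list of `ms_mention`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    out[[rec$sent_id]] <- lapply(rec$entities %||% list(),
                                 mention_from_list, sent_id = rec$sent_id)
  }
  out
}
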