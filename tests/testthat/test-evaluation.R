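pred_of <- function(...) list(...)

test_that("mention matching is exact multiset matching", {
  g <- list(entity_mention("SAS", "scale"), entity_mention("SAS", "scale"),
            entity_mention("焦虑", "concept"))
  p_same <- g
  res <- match_mentions(p_same, g)
  expect_length(res$matched, 3)
  expect_length(res$unmatched_pred, 0)
  expect_length(res$unmatched_gold, 0)
  # one-character difference breaks the match on both sides
  res2 <- match_mentions(list(entity_mention("SAs", "scale")),
                         list(entity_mention("SAS", "scale")))
  expect_length(res2$matched, 0)
  expect_length(res2$unmatched_pred, 1)
  expect_length(res2$unmatched_gold, 1)
  # gold has the surface twice, prediction once -> one unmatched gold
  res3 <- match_mentions(list(entity_mention("SAS", "scale")), g)
  expect_length(res3$matched, 1)
  expect_length(res3$unmatched_gold, 2)
  # conservation per sentence
  expect_equal(length(res3$matched) + length(res3$unmatched_pred), 1)
  expect_equal(length(res3$matched) + length(res3$unmatched_gold), 3)
})

test_that("matching counts equal a brute-force double loop", {
  co <- fixture_corpus(12, seed = 61)
  ec <- error_config(p_drop = 0.3, p_spurious = 0.5, p_type_flip = 0.2,
                     seed = 12)
  for (s in corpus_sentences(co)) {
    pred <- perturb_gold(s, ec)
    res <- match_mentions(pred, s$mentions)
    # brute force: count multiset intersection of (surface, type) keys
    key <- function(m) paste0(m$etype, "|", m$surface)
    pk <- vapply(pred, key, character(1))
    gk <- vapply(s$mentions, key, character(1))
    tp_bf <- 0L
    left <- gk
    for (k in pk) {
      hit <- match(k, left)
      if (!is.na(hit)) {
        tp_bf <- tp_bf + 1L
        left <- left[-hit]
      }
    }
    expect_equal(length(res$matched), tp_bf)
    expect_equal(length(res$unmatched_pred), length(pk) - tp_bf)
    expect_equal(length(res$unmatched_gold), length(gk) - tp_bf)
  }
})

test_that("prf matches hand-computed counts and conventions", {
  gold <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "A量表评估。",
                list(entity_mention("A量表", "scale", 0L, 3L)))))))
  # TP=1, FP=1, FN=0 -> P=0.5, R=1, F1=2/3
  preds <- list(s1 = list(entity_mention("A量表", "scale"),
                          entity_mention("C量表", "scale")))
  m <- prf(preds, gold, "scale")
  expect_equal(unname(m), c(0.5, 1, 2 / 3))
  # no predictions, some gold -> all zero
  expect_equal(unname(prf(list(s1 = list()), gold, "scale")), c(0, 0, 0))
  # perfect predictions
  expect_equal(unname(prf(list(s1 = list(entity_mention("A量表", "scale"))),
                          gold, "scale")), c(1, 1, 1))
})

test_that("macro F1 is the unweighted mean", {
  expect_equal(macro_f1(c(0.5, 0.7, 0.9)), 0.7)
  expect_equal(macro_f1(c(1, 1, 1)), 1)
  expect_equal(macro_f1(0.42), 0.42)
  expect_error(macro_f1(numeric(0)), "empty")
})

test_that("score bounds and F1 inequality hold on perturbed corpora", {
  co <- fixture_corpus(15, seed = 63)
  gold <- co
  sents <- corpus_sentences(co)
  ec <- error_config(p_drop = 0.3, p_spurious = 0.4, p_type_flip = 0.2,
                     p_boundary = 0.2, seed = 21)
  preds <- stats::setNames(lapply(sents, perturb_gold, ec = ec),
                           vapply(sents, function(s) s$sent_id,
                                  character(1)))
  ev <- evaluate(preds, gold)
  for (i in seq_len(nrow(ev$per_type))) {
    row <- ev$per_type[i, ]
    expect_true(all(c(row$P, row$R, row$F1) >= 0))
    expect_true(all(c(row$P, row$R, row$F1) <= 1))
    expect_lte(row$F1, max(row$P, row$R) + 1e-12)
  }
  expect_gte(ev$macro_f1, 0)
  expect_lte(ev$macro_f1, 1)
})

test_that("error taxonomy assigns each unmatched item exactly one category", {
  gold <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "护理服务质量总体评价条目与焦虑自评量表(SAS)。",
                list(entity_mention("护理服务质量总体评价", "item", 0L, 10L),
                     entity_mention("焦虑自评量表(SAS)", "scale", 13L, 24L)))))))
  preds <- list(s1 = list(
    # correct surface, wrong type -> type error
    entity_mention("护理服务质量总体评价", "concept"),
    # gold surface without the trailing parenthesis -> boundary error
    entity_mention("焦虑自评量表", "scale"),
    # fabricated non-entity -> identification error
    entity_mention("研究对象", "scale")))
  ev <- evaluate(preds, gold)
  expect_equal(unname(ev$error_counts[c("identification", "type",
                                        "boundary", "missing")]),
               c(1L, 1L, 1L, 0L))
  cats <- ev$errors$category
  expect_equal(sort(cats), sort(c("identification", "type", "boundary")))
})

test_that("unpredicted gold mentions are missing; overlapped ones are not", {
  gold <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "MMSE与生活质量。",
                list(entity_mention("MMSE", "scale", 0L, 4L),
                     entity_mention("生活质量", "concept", 5L, 9L)))))))
  # nothing predicted at all -> both gold mentions missing
  ev0 <- evaluate(list(s1 = list()), gold)
  expect_equal(unname(ev0$error_counts["missing"]), 2L)
  expect_equal(ev0$per_type$R, c(0, 0, 0))
  # a boundary-error prediction overlapping MMSE suppresses its "missing"
  ev1 <- evaluate(list(s1 = list(entity_mention("MMSE与", "scale"))), gold)
  expect_equal(unname(ev1$error_counts["boundary"]), 1L)
  expect_equal(unname(ev1$error_counts["missing"]), 1L)
})

test_that("evaluate rejects unknown sentence ids and writes reports", {
  gold <- tiny_corpus()
  expect_error(evaluate(list(ghost = list()), gold), "unknown sent_id")
  sents <- corpus_sentences(gold)
  preds <- stats::setNames(lapply(sents, function(s) s$mentions),
                           vapply(sents, function(s) s$sent_id,
                                  character(1)))
  ev <- evaluate(preds, gold)
  expect_equal(ev$macro_f1, 1)
  expect_equal(nrow(ev$errors), 0)
  prefix <- file.path(withr::local_tempdir(), "report")
  write_eval_report(ev, prefix)
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(csv), 5)  # 3 types + macro + micro
  js <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(js$macro_f1, 1)
})

test_that("recall tracks the keep rate under seeded drop injection", {
  co <- generate_corpus(synthetic_config(n_documents = 120,
                                         sentences_per_doc = c(8, 8),
                                         seed = 65))
  sents <- corpus_sentences(co)
  n_gold <- sum(vapply(sents, function(s) length(s$mentions), integer(1)))
  expect_gte(n_gold, 1000)
  ec <- error_config(p_drop = 0.2, seed = 31)
  preds <- stats::setNames(lapply(sents, perturb_gold, ec = ec),
                           vapply(sents, function(s) s$sent_id,
                                  character(1)))
  ev <- evaluate(preds, co)
  expect_lt(abs(ev$micro[["R"]] - 0.8), 0.03)
  expect_equal(ev$micro[["P"]], 1)
})
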