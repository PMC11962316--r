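test_that("JSON-Lines round trip is the identity on valid corpora", {
  for (co in list(tiny_corpus(), fixture_corpus(5, seed = 3),
                  ms_corpus())) {
    path <- withr::local_tempfile(fileext = ".jsonl")
    write_corpus(co, path)
    expect_equal(read_corpus(path), co)
  }
  # empty corpus writes a zero-record file
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(ms_corpus(), path)
  expect_length(readLines(path), 0)
})

test_that("unanchored mentions survive serialization without offsets", {
  s <- ms_sentence("d1-s1", "d1", "SAS评分",
                   list(entity_mention("SAS", "scale")))
  co <- ms_corpus(list(ms_document("d1", sentences = list(s))))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path)
  expect_false(grepl("\"start\"", readLines(path)[1]))
  expect_equal(read_corpus(path), co)
})

test_that("validation rejects offset violations and mismatches", {
  bad <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "短句",
                list(entity_mention("短句子", "scale", 0L, 3L)))))),
    validate = FALSE)
  expect_error(validate_corpus(bad), "s1")
  mis <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "焦虑量表",
                list(entity_mention("抑郁", "concept", 0L, 2L)))))),
    validate = FALSE)
  expect_error(validate_corpus(mis), "mismatch")
  expect_error(
    ms_corpus(list(ms_document("d1"), ms_document("d1"))), "duplicate")
})

test_that("clue-word filtering keeps exactly the matching paragraphs", {
  doc <- ms_document("d1", paragraphs = list(
    list(section = "方法", text = "该量表包含三个维度"),
    list(section = "前言", text = "研究背景介绍"),
    list(section = "结果", text = "各维度与领域得分")))
  out <- filter_paragraphs(doc, c("维度"))
  expect_length(out$paragraphs, 2)
  expect_equal(out$paragraphs[[1]]$text, "该量表包含三个维度")
  # a paragraph matching several clue words is retained once
  multi <- filter_paragraphs(doc, c("维度", "领域"))
  expect_length(multi$paragraphs, 2)
  # no matches anywhere -> empty paragraph list
  none <- filter_paragraphs(doc, c("条目"))
  expect_length(none$paragraphs, 0)
})

test_that("sentence splitting keeps delimiters and concatenates to input", {
  expect_equal(split_sentences("句一。句二？"), c("句一。", "句二？"))
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("无终结符"), "无终结符")
  cases <- c("甲。乙！丙；丁？戊\n己。", "。。", "a。b",
             "第一句。第二句没有结尾")
  for (x in cases) {
    expect_equal(paste(split_sentences(x), collapse = ""), x)
  }
})

test_that("document split reproduces the 90/10 arithmetic and partitions", {
  co <- fixture_corpus(720, seed = 1, sentences_per_doc = c(1, 1))
  sp <- split_documents(co, 0.9, seed = 2)
  expect_length(sp$train$documents, 648)
  expect_length(sp$test$documents, 72)
  ids <- function(x) vapply(x$documents, function(d) d$doc_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(co))
  # deterministic given the seed
  sp2 <- split_documents(co, 0.9, seed = 2)
  expect_identical(ids(sp$train), ids(sp2$train))
  # ratio 1 puts everything in train
  all_train <- split_documents(co, 1, seed = 2)
  expect_length(all_train$train$documents, 720)
  expect_length(all_train$test$documents, 0)
})

test_that("split partition property holds across ratios and seeds", {
  co <- fixture_corpus(23, seed = 5, sentences_per_doc = c(1, 2))
  for (ratio in c(0.1, 0.33, 0.5, 0.9)) {
    for (seed in 1:3) {
      sp <- split_documents(co, ratio, seed)
      expect_equal(length(sp$train$documents) + length(sp$test$documents),
                   23)
    }
  }
})

test_that("subsampling uses round-half-up sizes and is deterministic", {
  pool_big <- lapply(seq_len(20454), function(i)
    ms_sentence(paste0("s", i), paste0("d", i), "x"))
  expect_length(subsample_sentences(pool_big, 0.01, 1), 205)
  expect_length(subsample_sentences(pool_big, 0.05, 1), 1023)
  expect_length(subsample_sentences(pool_big, 0.1, 1), 2045)
  expect_length(subsample_sentences(pool_big, 0.5, 1), 10227)
  expect_identical(subsample_sentences(pool_big, 1.0, 1), pool_big)
  pool_small <- pool_big[1:100]
  for (f in c(0.01, 0.05, 0.1, 0.5, 1.0)) {
    expect_length(subsample_sentences(pool_small, f, 7),
                  floor(f * 100 + 0.5))
  }
  a <- subsample_sentences(pool_small, 0.3, 9)
  b <- subsample_sentences(pool_small, 0.3, 9)
  expect_identical(a, b)
  expect_error(subsample_sentences(pool_small, 0), "fraction")
  expect_error(subsample_sentences(pool_small, 1.2), "fraction")
})

test_that("corpus statistics count mentions per type and are order-invariant", {
  co <- tiny_corpus()
  st <- corpus_stats(co)
  get <- function(q) st$n[st$quantity == q]
  expect_equal(get("papers"), 2)
  expect_equal(get("sentences"), 3)
  expect_equal(get("mentions_scale"), 1)
  expect_equal(get("mentions_concept"), 2)
  expect_equal(get("mentions_item"), 1)
  expect_equal(get("mentions_total"), 4)
  rev_co <- ms_corpus(rev(co$documents))
  expect_equal(corpus_stats(rev_co)$n, st$n)
  empty <- corpus_stats(ms_corpus())
  expect_true(all(empty$n == 0))
})

test_that("Cohen kappa matches direct formula evaluation", {
  a <- rep("O", 10); a[c(1, 2)] <- "S"
  b <- rep("O", 10); b[c(1, 3)] <- "S"
  # p_o = 0.8; p_e = 0.2*0.2 + 0.8*0.8 = 0.68; kappa = 0.12/0.32
  expect_equal(cohen_kappa(a, b), 0.375)
  expect_equal(cohen_kappa(letters[1:5], letters[1:5]), 1)
  # complete disagreement with constant annotators is <= 0
  expect_lte(cohen_kappa(rep("S", 8), rep("O", 8)), 0)
  expect_error(cohen_kappa(c("a", "b"), c("a")), "length")
  expect_warning(k1 <- cohen_kappa(rep("O", 4), rep("O", 4)), "constant")
  expect_equal(k1, 1)
  # invariant under consistent relabeling
  relab <- c(S = "X", O = "Y")
  expect_equal(cohen_kappa(relab[a], relab[b]), cohen_kappa(a, b))
})

test_that("annotation kappa supports full-BIO and per-type modes", {
  co <- tiny_corpus()
  expect_equal(annotation_kappa(co, co), 1)
  # second annotator drops the item mention
  co2 <- tiny_corpus()
  co2$documents[[1]]$sentences[[2]]$mentions <- list()
  k_all <- annotation_kappa(co, co2)
  expect_lt(k_all, 1)
  expect_equal(annotation_kappa(co, co2, etype = "concept"), 1)
})

test_that("CoNLL export writes character-level BIO tags", {
  s <- ms_sentence("s1", "d1", "SAS评分",
                   list(entity_mention("SAS", "scale", 0L, 3L)))
  co <- ms_corpus(list(ms_document("d1", sentences = list(s))))
  path <- withr::local_tempfile(fileext = ".conll")
  export_conll(co, path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_equal(lines[1:5], c("S\tB-scale", "A\tI-scale", "S\tI-scale",
                             "评\tO", "分\tO"))
  # overlap -> error
  bad <- ms_corpus(list(ms_document("d1", sentences = list(
    ms_sentence("s1", "d1", "SAS评分",
                list(entity_mention("SAS", "scale", 0L, 3L),
                     entity_mention("AS评", "concept", 1L, 4L)))))),
    validate = FALSE)
  expect_error(export_conll(bad, withr::local_tempfile()), "overlap")
})
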