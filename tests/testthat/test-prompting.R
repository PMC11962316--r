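test_that("type prompt contains the four components in order", {
  p <- render_type_prompt(sentence_text = "本量表评估焦虑。")
  expect_s3_class(p, "ms_prompt")
  pos <- vapply(c("Task:", "Entity definitions:", "Output format:",
                  "Input text:"), function(x) regexpr(x, p$body, fixed = TRUE),
                integer(1))
  expect_true(all(diff(pos) > 0))
  for (t in entity_types()) expect_match(p$body, paste0("- ", t, ":"))
  expect_match(p$body, "{null}", fixed = TRUE)
  # injective in the input
  expect_false(identical(render_type_prompt(sentence_text = "a")$text,
                         render_type_prompt(sentence_text = "b")$text))
  # deterministic
  expect_identical(render_type_prompt(sentence_text = "a")$text,
                   render_type_prompt(sentence_text = "a")$text)
})

test_that("type responses parse by brace group with free-text fallback", {
  expect_setequal(parse_type_response("{scale, concept}"),
                  c("scale", "concept"))
  expect_length(parse_type_response("{null}"), 0)
  expect_equal(parse_type_response("The types are: scale."), "scale")
  expect_length(parse_type_response("没有实体。"), 0)
  expect_length(parse_type_response(""), 0)
  expect_setequal(parse_type_response("{SCALE,Item}"), c("scale", "item"))
  # no duplicates even when a type is repeated
  expect_equal(parse_type_response("{scale, scale}"), "scale")
})

test_that("marker rendering wraps mentions and rejects overlap", {
  m <- list(entity_mention("SAS", "scale", 0L, 3L))
  expect_equal(render_marked("SAS评分", m), "[[scale]]SAS[[/scale]]评分")
  expect_equal(render_marked("无实体句", list()), "无实体句")
  # adjacent mentions both wrapped in order
  two <- list(entity_mention("甲乙", "scale", 0L, 2L),
              entity_mention("丙丁", "concept", 2L, 4L))
  expect_equal(render_marked("甲乙丙丁", two),
               "[[scale]]甲乙[[/scale]][[concept]]丙丁[[/concept]]")
  over <- list(entity_mention("甲乙", "scale", 0L, 2L),
               entity_mention("乙丙", "concept", 1L, 3L))
  expect_error(render_marked("甲乙丙", over), "overlap")
  expect_error(render_marked("甲乙", list(entity_mention("甲", "scale"))),
               "anchored")
})

test_that("marked parsing anchors offsets and degrades gracefully", {
  out <- parse_marked("[[scale]]SAS[[/scale]]评分", "SAS评分")
  expect_equal(mention_df(out),
               data.frame(surface = "SAS", etype = "scale", start = 0L,
                          end = 3L, stringsAsFactors = FALSE))
  expect_length(parse_marked("没有任何标记", "没有任何标记"), 0)
  # LLM rewrote surrounding text but kept the marked span intact
  mut <- parse_marked("模型输出：[[scale]]SAS[[/scale]]是一个量表",
                      "检测SAS评分")
  expect_equal(mut[[1]]$start, 2L)
  expect_equal(mut[[1]]$end, 5L)
  # surface absent from the original stays unanchored
  expect_warning(
    gone <- parse_marked("[[scale]]不存在的量表[[/scale]]", "原句"),
    "unanchored")
  expect_true(is.na(gone[[1]]$start))
  expect_equal(gone[[1]]$surface, "不存在的量表")
  # unknown types and unbalanced markers are skipped with warnings
  expect_warning(u <- parse_marked("[[drug]]阿司匹林[[/drug]]", "阿司匹林"),
                 "unknown")
  expect_length(u, 0)
  expect_warning(b <- parse_marked("[[scale]]未闭合", "未闭合"), "unclosed")
  expect_length(b, 0)
})

test_that("repeated surfaces re-anchor at their own positions", {
  text <- "焦虑与焦虑自评量表"
  ms <- list(entity_mention("焦虑", "concept", 0L, 2L),
             entity_mention("焦虑自评量表", "scale", 3L, 9L))
  expect_equal(parse_marked(render_marked(text, ms), text), ms)
  # a single mention whose surface also occurs earlier in the text
  late <- list(entity_mention("焦虑", "concept", 3L, 5L))
  expect_equal(parse_marked(render_marked(text, late), text), late)
})

test_that("marker round trip holds corpus-wide", {
  co <- fixture_corpus(25, seed = 77)
  for (s in corpus_sentences(co)) {
    expect_equal(parse_marked(render_marked(s$text, s$mentions), s$text),
                 s$mentions)
  }
})

test_that("parser never raises on fuzzed input", {
  pieces <- c("[[", "]]", "[[scale]]", "[[/scale]]", "[[concept]]",
              "[[/item]]", "评分", "SAS", "量表", "{null}", "。", "x",
              "[[bogus]]", "\n", "[")
  withr::with_seed(4242, {
    for (i in 1:300) {
      raw <- paste(sample(pieces, sample(1:12, 1), replace = TRUE),
                   collapse = "")
      expect_no_error(suppressWarnings(parse_marked(raw, "SAS评分量表")))
    }
  })
})

test_that("label prompt shows demonstrations in ascending similarity", {
  pool <- corpus_sentences(fixture_corpus(8, seed = 3))
  idx <- build_index(pool, toy_encoder(32))
  demos <- retrieve(idx, pool[[1]]$text, 3)
  p <- render_label_prompt(demonstrations = demos,
                           predicted_types = c("scale", "concept"),
                           sentence_text = "待标注句。")
  expect_equal(length(gregexpr("Example [0-9]+:", p$body)[[1]]), 3)
  # most similar demonstration appears last (closest to the input)
  pos_most <- regexpr(demos[[1]]$sentence$text, p$body, fixed = TRUE)
  pos_least <- regexpr(demos[[3]]$sentence$text, p$body, fixed = TRUE)
  expect_gt(pos_most, pos_least)
  # pass-through of marked texts
  for (d in demos) expect_match(p$body, d$marked_text, fixed = TRUE)
  # zero-shot prompt is valid
  p0 <- render_label_prompt(demonstrations = list(),
                            predicted_types = "scale",
                            sentence_text = "句子。")
  expect_match(p0$body, "(no examples)", fixed = TRUE)
  expect_error(render_label_prompt(predicted_types = character(0)))
})

test_that("verification prompts and parsing follow the Yes/No contract", {
  m <- entity_mention("焦虑", "concept", 0L, 2L)
  p <- render_verify_prompt(m, "焦虑自评量表。")
  expect_match(p$body, "焦虑", fixed = TRUE)
  expect_match(p$body, "焦虑自评量表。", fixed = TRUE)
  ex <- list(list(mention = m, sentence = "焦虑很常见。", verdict = "Yes"),
             list(mention = m, sentence = "别的句子。", verdict = "No"))
  pe <- render_verify_prompt(m, "句。", ex)
  expect_equal(length(gregexpr("Answer:", pe$body)[[1]]), 2)

  expect_equal(parse_verify_response("No")$decision, "no")
  expect_equal(parse_verify_response("Yes, this is a scale name.")$decision,
               "yes")
  expect_equal(parse_verify_response("是")$decision, "yes")
  expect_equal(parse_verify_response("否")$decision, "no")
  expect_warning(v <- parse_verify_response("uncertain"), "defaulting")
  expect_equal(v$decision, "yes")
  # "no" inside a longer word does not count
  expect_equal(parse_verify_response("nothing but Yes")$decision, "yes")
})
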