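# Shared fixtures: small deterministic corpora and a brute-force
# retrieval oracle independent of the index implementation.

fixture_corpus <- function(n_documents = 10, seed = 42, ...) {
  generate_corpus(synthetic_config(n_documents = n_documents, seed = seed,
                                   ...))
}

# Hand-built two-document corpus with known mentions for exact-count tests.
tiny_corpus <- function() {
  s1 <- ms_sentence("d1-s1", "d1", "本研究采用焦虑自评量表评估焦虑。",
                    list(entity_mention("焦虑自评量表", "scale", 5L, 11L),
                         entity_mention("焦虑", "concept", 13L, 15L)))
  s2 <- ms_sentence("d1-s2", "d1", "入睡困难为常见条目。",
                    list(entity_mention("入睡困难", "item", 0L, 4L)))
  s3 <- ms_sentence("d2-s1", "d2", "结果显示睡眠质量较差。",
                    list(entity_mention("睡眠质量", "concept", 4L, 8L)))
  ms_corpus(list(
    ms_document("d1",
                paragraphs = list(list(section = "方法",
                                       text = "该量表包含三个维度。")),
                sentences = list(s1, s2)),
    ms_document("d2",
                paragraphs = list(list(section = "结果",
                                       text = "研究背景介绍。")),
                sentences = list(s3))))
}

# Exhaustive cosine ranking: the independent oracle for retrieve().
# Recomputes every pairwise similarity with cosine_similarity() on
# re-encoded texts and sorts with the same tie rule (smaller index first).
brute_force_ranking <- function(pool, enc, query_text,
                                required_types = NULL) {
  q <- enc$fn(query_text)
  sims <- vapply(pool, function(s) cosine_similarity(enc$fn(s$text), q),
                 numeric(1))
  ranking <- order(-round(sims, 9), seq_along(pool))
  if (is.null(required_types) || length(required_types) == 0) {
    return(list(ranking = ranking, sims = sims))
  }
  tsets <- lapply(pool, function(s)
    unique(vapply(s$mentions, function(m) m$etype, character(1))))
  qual <- vapply(tsets, function(ts) all(required_types %in% ts), logical(1))
  over <- vapply(tsets, function(ts)
    length(intersect(ts, required_types)) > 0, logical(1))
  tiers <- c(ranking[qual[ranking]], ranking[over[ranking]], ranking)
  list(ranking = tiers[!duplicated(tiers)], sims = sims)
}

mention_df <- function(mentions) {
  data.frame(
    surface = vapply(mentions, function(m) m$surface, character(1)),
    etype = vapply(mentions, function(m) m$etype, character(1)),
    start = vapply(mentions, function(m) m$start %||% NA_integer_,
                   integer(1)),
    end = vapply(mentions, function(m) m$end %||% NA_integer_, integer(1)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
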