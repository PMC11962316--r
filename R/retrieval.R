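# kNN demonstration retrieval over sentence embeddings with
# type-conditioned candidate pools.

#' Cosine similarity
#'
#' @param u,v Numeric vectors of equal dimension with nonzero norm.
#' @return `u . v / (|u| |v|)`, in \eqn{[-1, 1]}.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("cosine_similarity: dimension mismatch")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine_similarity: zero vector")
  sum(u * v) / (nu * nv)
}

new_demonstration <- function(sentence, marked_text) {
  structure(
    list(sentence = sentence,
         marked_text = marked_text,
         type_set = sort(unique(vapply(sentence$mentions,
                                       function(m) m$etype, character(1))))),
    class = "ms_demonstration"
  )
}

#' Build a demonstration index from a training pool
#'
#' Each gold-annotated training sentence becomes a demonstration: the raw
#' sentence, its marker-rendered labeled form (see [render_marked()]), and
#' the set of entity types it contains. Sentence embeddings are computed
#' once, L2-normalized and stored as a matrix so that retrieval reduces to
#' an inner product with the query embedding.
#'
#' @param pool List of `ms_sentence` with anchored gold mentions.
#' @param enc An `ms_encoder`.
#' @return An object of class `ms_demo_index`.
#' @export
build_index <- function(pool, enc = toy_encoder()) {
  if (length(pool) == 0) {
    warning("build_index: empty training pool")
  }
  demos <- lapply(pool, function(s)
    new_demonstration(s, render_marked(s$text, s$mentions)))
  emb <- encode_texts(enc, vapply(pool, function(s) s$text, character(1)))
  structure(
    list(demonstrations = demos, embeddings = emb, encoder = enc,
         sent_ids = vapply(pool, function(s) s$sent_id, character(1)),
         doc_ids = vapply(pool, function(s) s$doc_id, character(1))),
    class = "ms_demo_index"
  )
}

#' Retrieve the k nearest demonstrations for a query sentence
#'
#' Candidates are ranked by descending cosine similarity between the query
#' embedding and the stored demonstration embeddings, ties broken by smaller
#' demonstration index. With `required_types` given, the candidate pool is
#' first restricted to demonstrations whose type set contains all required
#' types (`type_match = "superset"`, the default) or equals them exactly
#' (`"exact"`). If fewer than `k` candidates qualify, the restriction is
#' relaxed in two stages — demonstrations sharing at least one required type,
#' then the whole pool — appending without duplicates until `k` results or
#' exhaustion, so a scarce type never silently yields fewer examples than
#' the pool can offer.
#'
#' @param index An `ms_demo_index`.
#' @param query_text Query sentence text.
#' @param k Number of demonstrations to return (`k = 0` gives an empty
#'   list).
#' @param required_types Optional character vector of entity types the
#'   demonstrations must cover.
#' @param type_match `"superset"` or `"exact"`.
#' @return List of demonstrations, each with `similarity` and `index`
#'   fields filled in, ranked most similar first.
#' @export
retrieve <- function(index, query_text, k, required_types = NULL,
                     type_match = c("superset", "exact")) {
  stopifnot(inherits(index, "ms_demo_index"))
  type_match <- match.arg(type_match)
  if (!is.numeric(k) || k < 0) stop("retrieve: k must be >= 0")
  k <- as.integer(k)
  n <- length(index$demonstrations)
  if (k == 0 || n == 0) return(list())

  q <- index$encoder$fn(query_text)
  qn <- sqrt(sum(q^2))
  if (qn == 0) {
    q[1] <- 1
    qn <- 1
  }
  sims <- as.vector(index$embeddings %*% (q / qn))
  # snap to 9 decimals before ranking so exact ties (equal vectors) are
  # broken by index, not by summation-order noise
  ranking <- order(-round(sims, 9), seq_len(n))

  tiers <- list(ranking)
  if (!is.null(required_types) && length(required_types) > 0) {
    required_types <- unique(required_types)
    qualifies <- vapply(index$demonstrations, function(d) {
      if (type_match == "exact") setequal(d$type_set, required_types)
      else all(required_types %in% d$type_set)
    }, logical(1))
    overlaps <- vapply(index$demonstrations, function(d)
      length(intersect(d$type_set, required_types)) > 0, logical(1))
    tiers <- list(ranking[qualifies[ranking]],
                  ranking[overlaps[ranking]],
                  ranking)
  }

  chosen <- integer(0)
  for (tier in tiers) {
    if (length(chosen) >= k) break
    chosen <- c(chosen, setdiff(tier, chosen))
  }
  chosen <- chosen[seq_len(min(k, length(chosen)))]
  lapply(chosen, function(i) {
    d <- index$demonstrations[[i]]
    d$similarity <- sims[i]
    d$index <- i
    d
  })
}

#' Persist a demonstration index as plain-text sidecar files
#'
#' Writes `manifest.json` (encoder name and dimension, pool size, hash of
#' the pool sentence ids), `pool.jsonl` (the training sentences in corpus
#' JSON-Lines format, one single-sentence document per line) and
#' `embeddings.tsv` (one row per demonstration).
#'
#' @param index An `ms_demo_index`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    encoder = index$encoder$name,
    dim = index$encoder$dim,
    n = length(index$demonstrations),
    pool_hash = str_hash(paste(index$sent_ids, collapse = "|"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  pool <- lapply(index$demonstrations, function(d) d$sentence)
  doc_of <- vapply(pool, function(s) s$doc_id, character(1))
  by_doc <- split(pool, factor(doc_of, levels = unique(doc_of)))
  docs <- lapply(names(by_doc), function(id)
    ms_document(id, sentences = by_doc[[id]]))
  write_corpus(ms_corpus(docs, validate = FALSE), file.path(dir, "pool.jsonl"))
  utils::write.table(index$embeddings, file.path(dir, "embeddings.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Load a demonstration index saved by [save_index()]
#'
#' The encoder itself is not serialized; pass the same encoder that built
#' the index. The manifest is checked against it and against the stored
#' pool.
#'
#' @param dir Directory written by [save_index()].
#' @param enc The `ms_encoder` the index was built with.
#' @return An `ms_demo_index`.
#' @export
load_index <- function(dir, enc) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(manifest$encoder, enc$name) ||
      manifest$dim != enc$dim) {
    stop("load_index: index was built with encoder '", manifest$encoder,
         "' (dim ", manifest$dim, "), got '", enc$name, "' (dim ",
         enc$dim, ")")
  }
  pool <- corpus_sentences(read_corpus(file.path(dir, "pool.jsonl")))
  # restore original doc ids stripped of the serialization prefix
  pool <- lapply(pool, function(s) s)
  idx <- build_index(pool, enc)
  stored <- as.matrix(utils::read.table(file.path(dir, "embeddings.tsv"),
                                        sep = "\t"))
  if (!isTRUE(all.equal(unname(stored), unname(idx$embeddings),
                        tolerance = 1e-6))) {
    stop("load_index: stored embeddings disagree with re-encoded pool")
  }
  idx
}
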