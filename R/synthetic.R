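# Synthetic corpus generation, a deterministic toy sentence encoder, and
# gold perturbation for the playback backend.

default_lexicons <- function() {
  list(
    scale = c(
      "焦虑自评量表(SAS)", "抑郁自评量表(SDS)", "匹兹堡睡眠质量指数量表",
      "SF-36健康调查简表", "汉密尔顿焦虑量表", "生活质量综合评定问卷",
      "护理工作满意度量表", "简易精神状态检查量表", "社会支持评定量表",
      "安德森症状评估量表", "心理弹性量表(CD-RISC)", "老年抑郁量表(GDS)"
    ),
    concept = c(
      "焦虑", "抑郁", "睡眠质量", "生活质量", "认知功能", "社会支持",
      "自我效能", "心理韧性", "疲乏", "疼痛程度", "照顾者负担", "服药依从性"
    ),
    item = c(
      "我感到心情愉快", "入睡困难", "我对未来充满信心", "我经常感到疲乏",
      "我能集中注意力", "我觉得自己有价值", "夜间易醒", "我与家人关系融洽"
    )
  )
}

synthetic_fillers <- function() {
  c("本研究采用", "结果显示，", "研究对象的", "该量表用于评估",
    "各维度得分表明，", "分析提示，", "由专业人员测评", "得分越高提示",
    "条目水平上，", "信度分析显示", "在本组患者中", "与常模相比，")
}

#' Configuration for the synthetic corpus generator
#'
#' Describes the structural parameters of the generated fixture corpora:
#' documents made of Methods/Results/Discussion-style paragraphs, sentences
#' with Chinese punctuation, and 0-3 typed entity mentions per sentence with
#' a type mix dominated by scale and concept mentions and a small item share
#' (defaults 0.45/0.43/0.12, mirroring the mention-type proportions of a
#' corpus of scale-development papers).
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Length-2 inclusive range for sentences per
#'   document.
#' @param type_weights Named probabilities over [entity_types()]; must sum
#'   to 1.
#' @param mentions_per_sentence Length-2 inclusive range (within 0-3) for
#'   mentions per sentence.
#' @param mention_count_probs Probabilities for each mention count in the
#'   range; default favors 1-2 mentions (about 1.25 per sentence on
#'   average).
#' @param lexicons Named list (per type) of candidate entity surfaces.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `ms_synth_config`.
#' @export
synthetic_config <- function(n_documents = 10L,
                             sentences_per_doc = c(3L, 8L),
                             type_weights = c(scale = 0.45, concept = 0.43,
                                              item = 0.12),
                             mentions_per_sentence = c(0L, 3L),
                             mention_count_probs = NULL,
                             lexicons = default_lexicons(),
                             seed = 1L) {
  stopifnot(n_documents >= 0, length(sentences_per_doc) == 2,
            all(sentences_per_doc >= 0),
            length(mentions_per_sentence) == 2,
            mentions_per_sentence[1] >= 0, mentions_per_sentence[2] <= 3)
  if (abs(sum(type_weights) - 1) > 1e-8) {
    stop("synthetic_config: type_weights must sum to 1")
  }
  if (!setequal(names(type_weights), entity_types())) {
    stop("synthetic_config: type_weights must name exactly ",
         paste(entity_types(), collapse = ", "))
  }
  for (t in entity_types()) {
    if (type_weights[[t]] > 0 && length(lexicons[[t]]) == 0) {
      stop("synthetic_config: empty lexicon for type '", t,
           "' with positive weight")
    }
  }
  counts <- seq(mentions_per_sentence[1], mentions_per_sentence[2])
  if (is.null(mention_count_probs)) {
    mention_count_probs <- c(0.25, 0.4, 0.2, 0.15)[seq_along(counts)]
    mention_count_probs <- mention_count_probs / sum(mention_count_probs)
  }
  stopifnot(length(mention_count_probs) == length(counts))
  structure(
    list(n_documents = as.integer(n_documents),
         sentences_per_doc = as.integer(sentences_per_doc),
         type_weights = type_weights[entity_types()],
         mentions_per_sentence = as.integer(mentions_per_sentence),
         mention_count_probs = mention_count_probs,
         lexicons = lexicons, seed = as.integer(seed)),
    class = "ms_synth_config"
  )
}

#' Read a synthetic-generator configuration from YAML or JSON
#'
#' @param path Path to a YAML or JSON file whose keys match the arguments of
#'   [synthetic_config()].
#' @return An `ms_synth_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$type_weights)) raw$type_weights <- unlist(raw$type_weights)
  do.call(synthetic_config, raw)
}

# Build one sentence: alternate filler clauses and entity surfaces, tracking
# code-point offsets as we go, and close with a Chinese full stop.
build_sentence <- function(sent_id, doc_id, etypes, lexicons) {
  fillers <- synthetic_fillers()
  text <- fillers[sample.int(length(fillers), 1)]
  mentions <- list()
  for (t in etypes) {
    surface <- lexicons[[t]][sample.int(length(lexicons[[t]]), 1)]
    start <- n_cp(text)
    text <- paste0(text, surface)
    mentions[[length(mentions) + 1L]] <-
      entity_mention(surface, t, start, start + n_cp(surface))
    text <- paste0(text, fillers[sample.int(length(fillers), 1)])
  }
  text <- paste0(text, "。")
  ms_sentence(sent_id, doc_id, text, mentions)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the config seed; every mention is anchored and
#' consistent with its sentence text. The output is structurally faithful to
#' an annotated scale-development corpus (typed spans, Chinese punctuation,
#' document organization, type mix) without attempting linguistic realism.
#'
#' @param config An [synthetic_config()].
#' @return An `ms_corpus`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ms_synth_config"))
  withr::with_seed(config$seed, {
    sections <- c("方法", "结果", "讨论")
    counts <- seq(config$mentions_per_sentence[1],
                  config$mentions_per_sentence[2])
    docs <- vector("list", config$n_documents)
    for (i in seq_len(config$n_documents)) {
      doc_id <- sprintf("doc%04d", i)
      rng <- config$sentences_per_doc
      n_sent <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1)
      sents <- vector("list", n_sent)
      for (j in seq_len(n_sent)) {
        m <- sample(counts, 1, prob = config$mention_count_probs)
        etypes <- if (m > 0) {
          sample(entity_types(), m, replace = TRUE,
                 prob = config$type_weights)
        } else character(0)
        sents[[j]] <- build_sentence(sprintf("%s-s%03d", doc_id, j),
                                     doc_id, etypes, config$lexicons)
      }
      # Paragraphs: concatenated sentence runs tagged with section names,
      # so clue-word filtering has realistic input.
      paras <- list()
      k <- 1L
      while (k <= n_sent) {
        upper <- min(n_sent, k + 2L)
        ptext <- paste(vapply(sents[k:upper], function(s) s$text,
                              character(1)), collapse = "")
        paras[[length(paras) + 1L]] <-
          list(section = sections[(length(paras) %% 3L) + 1L], text = ptext)
        k <- upper + 1L
      }
      docs[[i]] <- ms_document(doc_id, paragraphs = paras, sentences = sents)
    }
    ms_corpus(docs, validate = FALSE)
  })
}

#' Deterministic toy sentence encoder (character-bigram hashing)
#'
#' Hashes every character bigram of the text into `dim` buckets and
#' L2-normalizes the count vector. Identical texts map to identical unit
#' vectors; texts sharing no bigrams map to (near-)orthogonal vectors. A
#' single-character text uses the character itself as its only token; the
#' empty string maps to a fixed basis vector. This is a structural stand-in
#' for a sentence-embedding model, adequate for exercising retrieval.
#'
#' @param text Input string.
#' @param dim Embedding dimension, at least 8.
#' @return Numeric unit-norm vector of length `dim`.
#' @export
toy_encode <- function(text, dim = 64L) {
  stopifnot(dim >= 8)
  v <- numeric(dim)
  cps <- utf8ToInt(enc2utf8(text))
  n <- length(cps)
  if (n == 0) {
    v[1] <- 1
    return(v)
  }
  tokens <- if (n == 1) list(cps) else
    lapply(seq_len(n - 1), function(i) cps[i:(i + 1)])
  for (tok in tokens) {
    h <- 7
    for (cp in tok) h <- (h * 31 + cp) %% 2147483647
    v[(h %% dim) + 1] <- v[(h %% dim) + 1] + 1
  }
  v / sqrt(sum(v^2))
}

#' Construct an encoder object
#'
#' An encoder is a named function contract: text in, fixed-dimension
#' unit-norm vector out. Any sentence-embedding model can be wrapped this
#' way; the default wraps [toy_encode()] so the pipeline runs offline.
#'
#' @param fn Function `(text) -> numeric vector` of length `dim`.
#' @param name Encoder identity string (recorded in index manifests).
#' @param dim Output dimension.
#' @return An object of class `ms_encoder`.
#' @export
encoder <- function(fn, name, dim) {
  structure(list(fn = fn, name = name, dim = as.integer(dim)),
            class = "ms_encoder")
}

#' @rdname encoder
#' @export
toy_encoder <- function(dim = 64L) {
  encoder(function(text) toy_encode(text, dim), paste0("toy-bigram-", dim), dim)
}

#' Encode a character vector of texts into an embedding matrix
#'
#' @param enc An `ms_encoder`.
#' @param texts Character vector.
#' @return Matrix with one unit-norm row per text.
#' @export
encode_texts <- function(enc, texts) {
  stopifnot(inherits(enc, "ms_encoder"))
  if (length(texts) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = enc$dim))
  }
  out <- t(vapply(texts, enc$fn, numeric(enc$dim), USE.NAMES = FALSE))
  nrm <- sqrt(rowSums(out^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    out[bad, 1] <- 1
    nrm[bad] <- 1
  }
  out / nrm
}

#' Error-injection configuration for the playback backend
#'
#' Operationalizes the four observed LLM error modes so the gold-playback
#' backend can emit controlled imperfect output: dropped (missing) entities,
#' spurious identifications, wrong types, and shifted boundaries, plus
#' erroneous "No" verdicts during self-verification.
#'
#' @param p_drop Probability a gold mention is omitted.
#' @param p_spurious Expected number of spurious mentions per gold mention.
#' @param p_type_flip Probability a kept mention receives a wrong type.
#' @param p_boundary Probability a kept mention's span is extended or
#'   truncated by 1-2 characters.
#' @param p_verify_no Probability self-verification answers "No" on a
#'   correct entity.
#' @param seed Integer seed; perturbation is deterministic per sentence.
#' @return An object of class `ms_error_config`.
#' @export
error_config <- function(p_drop = 0, p_spurious = 0, p_type_flip = 0,
                         p_boundary = 0, p_verify_no = 0, seed = 1L) {
  for (p in c(p_drop, p_type_flip, p_boundary, p_verify_no)) {
    stopifnot(p >= 0, p <= 1)
  }
  stopifnot(p_spurious >= 0)
  structure(
    list(p_drop = p_drop, p_spurious = p_spurious, p_type_flip = p_type_flip,
         p_boundary = p_boundary, p_verify_no = p_verify_no,
         seed = as.integer(seed)),
    class = "ms_error_config"
  )
}

# Occupied-span bookkeeping: does [start, end) clash with any kept span?
span_overlaps <- function(start, end, spans) {
  any(vapply(spans, function(sp) start < sp[2] && sp[1] < end, logical(1)))
}

#' Perturb a sentence's gold mentions
#'
#' Applies the error-injection model to one sentence: each gold mention is
#' dropped with `p_drop`; survivors get a wrong type with `p_type_flip` and
#' a 1-2 character boundary shift with `p_boundary` (kept within sentence
#' bounds and never overlapping another kept mention; shifts that cannot
#' satisfy this are abandoned). Spurious mentions (count Poisson with mean
#' `p_spurious * n_gold`) are cut from unoccupied stretches of the sentence
#' and typed at random, never duplicating a gold (surface, type) pair of the
#' sentence. Deterministic given the config seed and the sentence id; all
#' zero rates return the gold mentions unchanged.
#'
#' @param sentence An `ms_sentence` with anchored gold mentions.
#' @param ec An [error_config()].
#' @return List of `ms_mention`, sorted by start offset.
#' @export
perturb_gold <- function(sentence, ec = error_config()) {
  stopifnot(inherits(ec, "ms_error_config"))
  gold <- sentence$mentions
  if (ec$p_drop == 0 && ec$p_spurious == 0 && ec$p_type_flip == 0 &&
      ec$p_boundary == 0) {
    return(gold)
  }
  len <- n_cp(sentence$text)
  gold_keys <- vapply(gold, function(m) paste0(m$etype, "\r", m$surface),
                      character(1))
  withr::with_seed(derive_seed(ec$seed, "perturb", sentence$sent_id), {
    keep <- if (length(gold)) stats::runif(length(gold)) >= ec$p_drop else
      logical(0)
    out <- list()
    spans <- list()
    for (i in seq_along(gold)) {
      if (!keep[i]) next
      m <- gold[[i]]
      if (ec$p_type_flip > 0 && stats::runif(1) < ec$p_type_flip) {
        others <- setdiff(entity_types(), m$etype)
        m$etype <- others[sample.int(length(others), 1)]
      }
      if (ec$p_boundary > 0 && stats::runif(1) < ec$p_boundary &&
          mention_anchored(m)) {
        delta <- sample(c(-2L, -1L, 1L, 2L), 1)
        side <- sample(c("start", "end"), 1)
        ns <- m$start
        ne <- m$end
        if (side == "start") ns <- ns - delta else ne <- ne + delta
        if (ns >= 0 && ne <= len && ne > ns &&
            !span_overlaps(ns, ne, spans)) {
          m <- entity_mention(substr_cp(sentence$text, ns, ne), m$etype,
                              ns, ne)
        }
      }
      if (mention_anchored(m)) {
        spans[[length(spans) + 1L]] <- c(m$start, m$end)
      }
      out[[length(out) + 1L]] <- m
    }
    if (ec$p_spurious > 0 && length(gold) > 0) {
      n_sp <- stats::rpois(1, ec$p_spurious * length(gold))
      for (k in seq_len(n_sp)) {
        # enumerate free spans so a crowded sentence cannot silently bias
        # the realized spurious rate below its configured expectation
        for (w in sample(2:5)) {
          if (len - w < 1) next
          cand <- which(!vapply(seq_len(len - w), function(st)
            span_overlaps(st, st + w, spans), logical(1)))
          placed <- FALSE
          while (length(cand)) {
            pick <- sample.int(length(cand), 1)
            st <- cand[pick]
            en <- st + w
            surf <- substr_cp(sentence$text, st, en)
            ty_ok <- entity_types()[!(paste0(entity_types(), "\r", surf)
                                      %in% gold_keys)]
            if (length(ty_ok)) {
              ty <- ty_ok[sample.int(length(ty_ok), 1)]
              out[[length(out) + 1L]] <- entity_mention(surf, ty, st, en)
              spans[[length(spans) + 1L]] <- c(st, en)
              placed <- TRUE
              break
            }
            cand <- cand[-pick]
          }
          if (placed) break
        }
      }
    }
    starts <- vapply(out, function(m)
      if (mention_anchored(m)) m$start else .Machine$integer.max, integer(1))
    out[order(starts)]
  })
}
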