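# Corpus data model, JSON-Lines standoff I/O, corpus preparation and
# inter-annotator agreement.

#' Entity type inventory
#'
#' The three entity types recognized by the framework: `scale` (the official
#' or widely recognized title of a medical scale), `concept` (the broader
#' theoretical or clinical construct a scale assesses, e.g. anxiety), and
#' `item` (an individual question within a scale).
#'
#' @return Character vector of the three type names.
#' @export
entity_types <- function() c("scale", "concept", "item")

#' Create an entity mention
#'
#' A typed surface string, optionally anchored in its sentence by character
#' offsets. Offsets count Unicode code points (not bytes), are 0-based and
#' half-open, so `substr(text, start + 1, end)` recovers the surface.
#'
#' @param surface Surface string of the mention.
#' @param etype Entity type, one of [entity_types()].
#' @param start,end Integer code-point offsets (0-based half-open), or `NA`
#'   for an unanchored mention (e.g. parsed from LLM output that could not be
#'   located in the original sentence).
#' @return An object of class `ms_mention`.
#' @export
entity_mention <- function(surface, etype, start = NA_integer_, end = NA_integer_) {
  etype <- match.arg(etype, entity_types())
  if (!is.na(start) && !is.na(end) && end <= start) {
    stop("entity_mention: end must be > start (got [", start, ", ", end, "))")
  }
  structure(
    list(surface = enc2utf8(surface), etype = etype,
         start = if (is.na(start)) NA_integer_ else as.integer(start),
         end = if (is.na(end)) NA_integer_ else as.integer(end)),
    class = "ms_mention"
  )
}

mention_anchored <- function(m) !is.na(m$start) && !is.na(m$end)

#' Create a sentence
#'
#' @param sent_id Corpus-unique sentence identifier.
#' @param doc_id Identifier of the owning document.
#' @param text Sentence text (UTF-8).
#' @param mentions List of [entity_mention()] objects.
#' @return An object of class `ms_sentence`.
#' @export
ms_sentence <- function(sent_id, doc_id, text, mentions = list()) {
  structure(
    list(sent_id = sent_id, doc_id = doc_id, text = enc2utf8(text),
         mentions = mentions),
    class = "ms_sentence"
  )
}

#' Create a document
#'
#' @param doc_id Corpus-unique document identifier.
#' @param paragraphs List of paragraphs, each a list with `section` and
#'   `text` fields.
#' @param sentences List of [ms_sentence()] objects belonging to this
#'   document.
#' @return An object of class `ms_document`.
#' @export
ms_document <- function(doc_id, paragraphs = list(), sentences = list()) {
  structure(
    list(doc_id = doc_id, paragraphs = paragraphs, sentences = sentences),
    class = "ms_document"
  )
}

#' Create a corpus
#'
#' A corpus is a list of documents; each document holds its paragraphs and
#' its gold-annotated sentences. Splitting for train/test is done at the
#' document level so no document contributes sentences to both sides.
#'
#' @param documents List of [ms_document()] objects.
#' @param validate Check all invariants (unique ids, offsets consistent with
#'   sentence text). Default `TRUE`.
#' @return An object of class `ms_corpus`.
#' @export
ms_corpus <- function(documents = list(), validate = TRUE) {
  x <- structure(list(documents = documents), class = "ms_corpus")
  if (validate) validate_corpus(x)
  x
}

#' Validate corpus invariants
#'
#' Checks doc_id uniqueness, corpus-wide sent_id uniqueness, that each
#' sentence's `doc_id` matches its owning document, and that every anchored
#' mention satisfies `text[start:end] == surface` on code points.
#'
#' @param corpus An `ms_corpus`.
#' @return The corpus, invisibly. Errors on the first violation.
#' @export
validate_corpus <- function(corpus) {
  doc_ids <- vapply(corpus$documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(doc_ids)) {
    stop("validate_corpus: duplicate doc_id: ",
         doc_ids[duplicated(doc_ids)][1])
  }
  sent_ids <- character(0)
  for (d in corpus$documents) {
    for (s in d$sentences) {
      if (!identical(s$doc_id, d$doc_id)) {
        stop("validate_corpus: sentence ", s$sent_id,
             " has doc_id ", s$doc_id, " inside document ", d$doc_id)
      }
      len <- n_cp(s$text)
      for (m in s$mentions) {
        if (!mention_anchored(m)) next
        if (m$start < 0 || m$end > len) {
          stop("validate_corpus: mention offsets [", m$start, ", ", m$end,
               ") outside sentence ", s$sent_id, " (length ", len, ")")
        }
        got <- substr_cp(s$text, m$start, m$end)
        if (!identical(got, m$surface)) {
          stop("validate_corpus: offset/surface mismatch in sentence ",
               s$sent_id, ": text[", m$start, ":", m$end, "] = '", got,
               "' but surface = '", m$surface, "'")
        }
      }
      sent_ids <- c(sent_ids, s$sent_id)
    }
  }
  if (anyDuplicated(sent_ids)) {
    stop("validate_corpus: duplicate sent_id: ",
         sent_ids[duplicated(sent_ids)][1])
  }
  invisible(corpus)
}

#' Flatten a corpus to its sentence pool
#'
#' @param corpus An `ms_corpus`.
#' @return Unnamed list of all sentences in document order.
#' @export
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus$documents, function(d) d$sentences), recursive = FALSE) %||% list()
}

mention_to_list <- function(m) {
  out <- list(text = m$surface, type = m$etype)
  if (mention_anchored(m)) {
    out$start <- m$start
    out$end <- m$end
  }
  out
}

mention_from_list <- function(x, sent_id) {
  if (is.null(x$text) || is.null(x$type)) {
    stop("corpus parse error: entity without text/type in sentence ", sent_id)
  }
  entity_mention(x$text, x$type,
                 start = x$start %||% NA_integer_,
                 end = x$end %||% NA_integer_)
}

#' Read a corpus from a JSON-Lines standoff file
#'
#' One document per line:
#' `{"doc_id", "paragraphs": [{"section", "text"}], "sentences":
#' [{"sent_id", "text", "entities": [{"start", "end", "text", "type"}]}]}`.
#' Offsets are 0-based half-open code-point offsets; `start`/`end` absent
#' means the mention is unanchored. All corpus invariants are validated on
#' load.
#'
#' @param path Path to a JSON-Lines file.
#' @return An `ms_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop("read_corpus: malformed record on line ", i,
                               ": ", conditionMessage(e))
    )
    if (is.null(rec$doc_id)) stop("read_corpus: missing doc_id on line ", i)
    sents <- lapply(rec$sentences %||% list(), function(s) {
      ms_sentence(
        sent_id = s$sent_id, doc_id = rec$doc_id, text = s$text,
        mentions = lapply(s$entities %||% list(), mention_from_list,
                          sent_id = s$sent_id)
      )
    })
    paras <- lapply(rec$paragraphs %||% list(), function(p) {
      list(section = p$section %||% "", text = enc2utf8(p$text %||% ""))
    })
    docs[[i]] <- ms_document(rec$doc_id, paragraphs = paras, sentences = sents)
  }
  ms_corpus(docs)
}

#' Write a corpus as JSON Lines
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c, path))`
#' reproduces `c` exactly, including unanchored mentions (serialized without
#' offsets).
#'
#' @param corpus An `ms_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in corpus$documents) {
    rec <- list(
      doc_id = d$doc_id,
      paragraphs = lapply(d$paragraphs, function(p)
        list(section = p$section, text = p$text)),
      sentences = lapply(d$sentences, function(s)
        list(sent_id = s$sent_id, text = s$text,
             entities = lapply(s$mentions, mention_to_list)))
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Default clue-word lexicon for paragraph filtering
#'
#' Clue words marking paragraphs likely to mention scales, measurement
#' concepts or items: dimension, domain, variable, concept, factor, item,
#' entry, plus their standard Chinese equivalents.
#'
#' @return Character vector of clue strings.
#' @export
clue_lexicon <- function() {
  c("dimension", "domain", "variable", "concept", "factor", "item", "entry",
    "维度", "领域", "变量", "概念",
    "因子", "因素", "条目", "词条")
}

#' Filter paragraphs by clue words
#'
#' Retains only the paragraphs of a document that contain at least one
#' lexicon string as a substring, preserving order. Entity-dense sections of
#' scale-development papers (Methods, Results, Discussion) are recognizable
#' by such clue words; the rest is dropped before annotation.
#'
#' @param document An `ms_document`.
#' @param lexicon Non-empty character vector of clue substrings; defaults to
#'   [clue_lexicon()].
#' @return The document with only matching paragraphs.
#' @export
filter_paragraphs <- function(document, lexicon = clue_lexicon()) {
  stopifnot(length(lexicon) > 0)
  keep <- vapply(document$paragraphs, function(p) {
    any(vapply(lexicon, function(w) grepl(w, p$text, fixed = TRUE), logical(1)))
  }, logical(1))
  document$paragraphs <- document$paragraphs[keep]
  document
}

#' Split a paragraph into sentences
#'
#' Rule-based splitting on Chinese terminal punctuation (full stop, question
#' mark, exclamation mark, semicolon) and newline. Each delimiter is retained
#' with the preceding sentence, so the concatenation of the output equals the
#' input.
#'
#' @param paragraph_text Input text.
#' @return Character vector of sentences (possibly empty).
#' @export
split_sentences <- function(paragraph_text) {
  text <- enc2utf8(paragraph_text)
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  terminals <- c("。", "？", "！", "；", "\n")  # 。？！；
  cuts <- which(chars %in% terminals)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(chars))
  keep <- starts <= ends
  vapply(which(keep), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Split a corpus into train and test at the document level
#'
#' Documents are shuffled by `seed` and the first
#' `floor(train_ratio * N + 0.5)` (round half up) go to training. A 720
#' document corpus at ratio 0.9 yields 648 training and 72 test documents.
#' The partition is disjoint, exhaustive, and deterministic given the seed.
#'
#' @param corpus An `ms_corpus`.
#' @param train_ratio Fraction of documents assigned to training, in (0, 1].
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` corpora.
#' @export
split_documents <- function(corpus, train_ratio = 0.9, seed = 1L) {
  stopifnot(train_ratio > 0, train_ratio <= 1)
  n <- length(corpus$documents)
  if (n == 0) {
    warning("split_documents: empty corpus")
    return(list(train = ms_corpus(validate = FALSE),
                test = ms_corpus(validate = FALSE)))
  }
  n_train <- min(n, round_half_up(train_ratio * n))
  perm <- withr::with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[-seq_len(n_train)])
  list(train = ms_corpus(corpus$documents[idx_train], validate = FALSE),
       test = ms_corpus(corpus$documents[idx_test], validate = FALSE))
}

#' Subsample a sentence pool
#'
#' Draws `floor(fraction * N + 0.5)` sentences without replacement (round
#' half up: a 20,454-sentence pool gives 205 at 1% and 1023 at 5%),
#' deterministically for a given seed. `fraction = 1` returns the pool
#' unchanged. Used to emulate low-resource training pools.
#'
#' @param pool List of sentences.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return List of sampled sentences, in original pool order.
#' @export
subsample_sentences <- function(pool, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("subsample_sentences: fraction must be in (0, 1]")
  }
  if (fraction == 1) return(pool)
  n <- length(pool)
  m <- min(n, round_half_up(fraction * n))
  idx <- withr::with_seed(seed, sample.int(n, m))
  pool[sort(idx)]
}

#' Corpus summary statistics
#'
#' @param corpus An `ms_corpus`.
#' @return A tibble with counts of papers, paragraphs, sentences, mentions
#'   per entity type, and total mentions.
#' @export
corpus_stats <- function(corpus) {
  sents <- corpus_sentences(corpus)
  types <- unlist(lapply(sents, function(s)
    vapply(s$mentions, function(m) m$etype, character(1))))
  type_counts <- vapply(entity_types(), function(t) sum(types == t), integer(1))
  tibble::tibble(
    quantity = c("papers", "paragraphs", "sentences",
                 paste0("mentions_", entity_types()), "mentions_total"),
    n = unname(c(length(corpus$documents),
          sum(vapply(corpus$documents, function(d) length(d$paragraphs),
                     integer(1))),
          length(sents),
          type_counts,
          sum(type_counts)))
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two annotators:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with observed agreement
#' \eqn{p_o} and expected agreement \eqn{p_e} computed from the marginal
#' label frequencies of each annotator.
#'
#' @param labels_a,labels_b Equal-length vectors of categorical labels.
#' @return Kappa in \eqn{[-1, 1]}. When both annotators assign one identical
#'   constant label (`p_e = 1`), agreement is perfect by construction and 1
#'   is returned with a warning.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("cohen_kappa: label sequences differ in length")
  }
  if (length(labels_a) < 1) stop("cohen_kappa: empty label sequences")
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  levs <- union(a, b)
  po <- mean(a == b)
  pa <- vapply(levs, function(l) mean(a == l), numeric(1))
  pb <- vapply(levs, function(l) mean(b == l), numeric(1))
  pe <- sum(pa * pb)
  if (pe >= 1) {
    warning("cohen_kappa: both annotators constant and identical; kappa = 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Character-level BIO labels for a sentence
#'
#' @param sentence An `ms_sentence` with anchored, non-overlapping mentions.
#' @param etype If given, binarize: characters of this type keep their B/I
#'   tags, all other characters become "O".
#' @return Character vector of per-character tags ("B-scale", "I-scale", ...,
#'   "O").
#' @export
bio_labels <- function(sentence, etype = NULL) {
  len <- n_cp(sentence$text)
  tags <- rep("O", len)
  ms <- Filter(mention_anchored, sentence$mentions)
  ms <- ms[order(vapply(ms, function(m) m$start, integer(1)))]
  prev_end <- 0L
  for (m in ms) {
    if (m$start < prev_end) {
      stop("bio_labels: overlapping mentions in sentence ", sentence$sent_id,
           " at offset ", m$start)
    }
    tags[m$start + 1L] <- paste0("B-", m$etype)
    if (m$end > m$start + 1L) {
      tags[(m$start + 2L):m$end] <- paste0("I-", m$etype)
    }
    prev_end <- m$end
  }
  if (!is.null(etype)) {
    tags[!grepl(paste0("-", etype, "$"), tags)] <- "O"
  }
  tags
}

#' Inter-annotator agreement between two annotations of the same text
#'
#' Computes Cohen's kappa on character-level BIO labels over sentences shared
#' (by `sent_id`) between the two corpora. With `etype` given, labels are
#' binarized to in-type vs out, yielding a per-type kappa.
#'
#' @param corpus_a,corpus_b Two `ms_corpus` annotations of identical texts.
#' @param etype Optional single entity type for per-type agreement.
#' @return Kappa value.
#' @export
annotation_kappa <- function(corpus_a, corpus_b, etype = NULL) {
  sa <- corpus_sentences(corpus_a)
  sb <- corpus_sentences(corpus_b)
  names(sa) <- vapply(sa, function(s) s$sent_id, character(1))
  names(sb) <- vapply(sb, function(s) s$sent_id, character(1))
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) stop("annotation_kappa: no shared sent_ids")
  la <- unlist(lapply(shared, function(id) bio_labels(sa[[id]], etype)))
  lb <- unlist(lapply(shared, function(id) bio_labels(sb[[id]], etype)))
  cohen_kappa(la, lb)
}

#' Export a corpus in character-level CoNLL BIO format
#'
#' One character per line (`char<TAB>tag`), blank line between sentences.
#' Requires every mention to be anchored and mentions within a sentence to be
#' non-overlapping.
#'
#' @param corpus An `ms_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_conll <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus_sentences(corpus)) {
    if (!all(vapply(s$mentions, mention_anchored, logical(1)))) {
      stop("export_conll: unanchored mention in sentence ", s$sent_id)
    }
    tags <- bio_labels(s)  # errors on overlap, naming the sentence
    chars <- strsplit(s$text, "")[[1]]
    writeLines(paste(chars, tags, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}
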