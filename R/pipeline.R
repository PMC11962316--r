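# Orchestration: the per-sentence three-step procedure and the
# experimental sweeps (k-shot, low-resource fractions, ablation arms).

#' Pipeline configuration
#'
#' The four ablation arms compose the framework incrementally:
#' * `baseline` — a single labeling call with `k` retrieved demonstrations
#'   (no type conditioning) asking for all entity types;
#' * `baseline_sv` — baseline plus the self-verification filter;
#' * `baseline_cot` — the two-step chain of thought: type recognition
#'   first, then labeling with type-conditioned retrieval;
#' * `full` — all three steps (type recognition, conditioned labeling,
#'   verification).
#'
#' @param mode One of the four arms above.
#' @param k Demonstrations per labeling prompt (`k = 0` degenerates to a
#'   zero-shot labeling prompt). Default 20, the best-performing shot count.
#' @param training_fraction Fraction of the training pool indexed, in
#'   (0, 1].
#' @param seed Seed governing pool subsampling and any other pipeline
#'   randomness.
#' @param n_verify_examples Few-shot examples synthesized for each
#'   verification prompt (from the retrieved demonstrations' gold entities,
#'   plus one corrupted "No" case). Default 4.
#' @param type_match Type-conditioning semantics for retrieval, see
#'   [retrieve()].
#' @param random_demos Baseline arms only: pick demonstrations uniformly at
#'   random instead of by similarity.
#' @return An object of class `ms_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("full", "baseline", "baseline_sv",
                                     "baseline_cot"),
                            k = 20L, training_fraction = 1, seed = 1L,
                            n_verify_examples = 4L,
                            type_match = "superset",
                            random_demos = FALSE) {
  mode <- match.arg(mode)
  stopifnot(k >= 0, training_fraction > 0, training_fraction <= 1)
  structure(
    list(mode = mode, k = as.integer(k),
         training_fraction = training_fraction, seed = as.integer(seed),
         n_verify_examples = as.integer(n_verify_examples),
         type_match = type_match, random_demos = random_demos),
    class = "ms_pipeline_config"
  )
}

uses_cot <- function(config) config$mode %in% c("baseline_cot", "full")
uses_verification <- function(config) config$mode %in% c("baseline_sv", "full")

# Few-shot verification examples built from the retrieved demonstrations:
# gold entities answer "Yes"; one corrupted case (type swapped) answers
# "No". Deterministic given the demonstrations.
verify_examples <- function(demos, n) {
  if (n <= 0 || length(demos) == 0) return(list())
  ex <- list()
  for (d in demos) {
    for (m in d$sentence$mentions) {
      ex[[length(ex) + 1L]] <- list(mention = m, sentence = d$sentence$text,
                                    verdict = "Yes")
      if (length(ex) >= n - 1L) break
    }
    if (length(ex) >= n - 1L) break
  }
  if (length(ex) > 0) {
    first <- ex[[1]]
    wrong <- first$mention
    wrong$etype <- setdiff(entity_types(), wrong$etype)[1]
    ex[[length(ex) + 1L]] <- list(mention = wrong, sentence = first$sentence,
                                  verdict = "No")
  }
  ex
}

#' Run the framework on one sentence
#'
#' Executes the steps dictated by the configured mode and returns the final
#' predictions together with a full trace (raw LLM texts, parsed results,
#' retrieved demonstration ids and similarities, per-mention verdicts).
#' When step 1 is active and returns the empty type set, the sentence
#' short-circuits to zero predictions with no further backend calls.
#'
#' @param sentence An `ms_sentence` (gold mentions, if present, are unused
#'   here) or a bare character string.
#' @param index An `ms_demo_index` built from the training pool.
#' @param backend An `ms_backend`.
#' @param config An [pipeline_config()].
#' @param defs Entity definitions for the prompts.
#' @param llm An [llm_config()].
#' @return List with `predictions` (list of `ms_mention`) and `trace`.
#' @export
run_sentence <- function(sentence, index, backend,
                         config = pipeline_config(),
                         defs = default_entity_definitions(),
                         llm = llm_config()) {
  if (is.character(sentence)) {
    sentence <- ms_sentence(paste0("adhoc-", str_hash(sentence)), "adhoc",
                            sentence)
  }
  trace <- list(sent_id = sentence$sent_id, mode = config$mode)

  # Step 1: zero-shot entity-type recognition (CoT arms only)
  if (uses_cot(config)) {
    p1 <- render_type_prompt(defs, sentence$text, sent_id = sentence$sent_id)
    raw1 <- complete(backend, p1, llm)
    types <- parse_type_response(raw1)
    trace$step1 <- list(raw = raw1, types = types)
    if (length(types) == 0) {
      trace$final <- list()
      return(list(predictions = list(), trace = trace))
    }
    required <- types
  } else {
    types <- entity_types()
    required <- NULL
  }

  # Demonstration retrieval
  demos <- if (config$random_demos && !uses_cot(config)) {
    n <- length(index$demonstrations)
    take <- withr::with_seed(
      derive_seed(config$seed, "demos", sentence$sent_id),
      sample.int(n, min(config$k, n)))
    lapply(take, function(i) {
      d <- index$demonstrations[[i]]
      d$similarity <- NA_real_
      d$index <- i
      d
    })
  } else {
    retrieve(index, sentence$text, config$k, required_types = required,
             type_match = config$type_match)
  }
  trace$demos <- tibble::tibble(
    sent_id = vapply(demos, function(d) d$sentence$sent_id, character(1)),
    similarity = vapply(demos, function(d) d$similarity, numeric(1)))

  # Step 2: few-shot marker labeling
  p2 <- render_label_prompt(defs, demos, types, sentence$text,
                            sent_id = sentence$sent_id)
  raw2 <- complete(backend, p2, llm)
  mentions <- parse_marked(raw2, sentence$text)
  trace$step2 <- list(raw = raw2, n_mentions = length(mentions))

  # Step 3: self-verification — drop every entity answered "No"
  if (uses_verification(config) && length(mentions) > 0) {
    ex <- verify_examples(demos, config$n_verify_examples)
    verdicts <- character(length(mentions))
    keep <- logical(length(mentions))
    for (i in seq_along(mentions)) {
      p3 <- render_verify_prompt(mentions[[i]], sentence$text, ex,
                                 sent_id = sentence$sent_id)
      raw3 <- complete(backend, p3, llm)
      v <- parse_verify_response(raw3)
      verdicts[i] <- v$decision
      keep[i] <- v$decision == "yes"
    }
    trace$verify <- tibble::tibble(
      surface = vapply(mentions, function(m) m$surface, character(1)),
      etype = vapply(mentions, function(m) m$etype, character(1)),
      verdict = verdicts)
    mentions <- mentions[keep]
  }

  trace$final <- mentions
  list(predictions = mentions, trace = trace)
}

#' Run the framework over a test set
#'
#' Subsamples the training pool to `training_fraction` (seeded, round half
#' up), builds the demonstration index, verifies that no test document
#' leaks into the pool, and processes every test sentence. Deterministic
#' given the seeds and a deterministic backend.
#'
#' @param test_sentences List of `ms_sentence` to predict on.
#' @param training_pool List of gold-annotated `ms_sentence` (disjoint from
#'   the test set at the document level).
#' @param backend An `ms_backend`.
#' @param config An [pipeline_config()].
#' @param enc An `ms_encoder`.
#' @param defs Entity definitions.
#' @param llm An [llm_config()].
#' @return List with `predictions` (named list `sent_id` to mentions),
#'   `traces`, and `n_pool` (indexed pool size after subsampling).
#' @export
run_corpus <- function(test_sentences, training_pool, backend,
                       config = pipeline_config(), enc = toy_encoder(),
                       defs = default_entity_definitions(),
                       llm = llm_config()) {
  test_docs <- unique(vapply(test_sentences, function(s) s$doc_id,
                             character(1)))
  pool_docs <- unique(vapply(training_pool, function(s) s$doc_id,
                             character(1)))
  shared <- intersect(test_docs, pool_docs)
  if (length(shared)) {
    stop("run_corpus: training pool and test set share document(s): ",
         paste(utils::head(shared, 3), collapse = ", "))
  }
  pool <- subsample_sentences(training_pool, config$training_fraction,
                              seed = config$seed)
  index <- build_index(pool, enc)

  test_ids <- vapply(test_sentences, function(s) s$sent_id, character(1))
  predictions <- stats::setNames(vector("list", length(test_sentences)),
                                 test_ids)
  traces <- vector("list", length(test_sentences))
  for (i in seq_along(test_sentences)) {
    res <- run_sentence(test_sentences[[i]], index, backend, config, defs,
                        llm)
    if (any(res$trace$demos$sent_id %in% test_ids)) {
      stop("run_corpus: leakage — retrieved demonstration is a test sentence")
    }
    predictions[[i]] <- res$predictions
    traces[[i]] <- res$trace
  }
  list(predictions = predictions, traces = traces, n_pool = length(pool))
}

eval_row <- function(report) {
  pt <- report$per_type
  out <- c(P = unname(report$micro["P"]), R = unname(report$micro["R"]),
           F1 = report$macro_f1)
  for (t in entity_types()) {
    row <- pt[pt$etype == t, ]
    out[paste0("F1_", t)] <- row$F1
  }
  out
}

#' Sweep the number of demonstrations (k-shot)
#'
#' Evaluates each `k` on a seeded random subsample of the test sentences
#' (default 100), holding everything else fixed. Returns one row per `k`
#' with overall precision/recall (micro), macro F1 and per-type F1.
#'
#' @param ks Integer vector of shot counts, e.g. `c(0, 5, 10, 15, 20, 25)`.
#' @param test_sentences,training_pool,backend,config,enc See
#'   [run_corpus()].
#' @param n_eval Size of the evaluation subsample.
#' @param seed Seed for the subsample.
#' @return A tibble, one row per `k`.
#' @export
sweep_kshot <- function(ks, test_sentences, training_pool, backend,
                        config = pipeline_config(), enc = toy_encoder(),
                        n_eval = 100L, seed = 1L) {
  stopifnot(length(ks) > 0)
  n <- length(test_sentences)
  take <- withr::with_seed(seed, sample.int(n, min(n_eval, n)))
  subset <- test_sentences[sort(take)]
  gold <- sentences_as_corpus(subset)
  rows <- lapply(ks, function(k) {
    cfg <- config
    cfg$k <- as.integer(k)
    res <- run_corpus(subset, training_pool, backend, cfg, enc)
    r <- eval_row(evaluate(res$predictions, gold))
    tibble::tibble(k = k, !!!as.list(r))
  })
  do.call(rbind, rows)
}

#' Sweep training-pool fractions (low-resource protocol)
#'
#' One row per fraction: the pool is subsampled (seeded, round half up),
#' the index rebuilt, and the full test set scored.
#'
#' @param fractions Numeric vector in (0, 1], e.g.
#'   `c(0.01, 0.05, 0.1, 0.5, 1)`.
#' @param test_sentences,training_pool,backend,config,enc See
#'   [run_corpus()].
#' @return A tibble with `fraction`, `n_sentences` (subsampled pool size)
#'   and the score columns.
#' @export
sweep_lowresource <- function(fractions, test_sentences, training_pool,
                              backend, config = pipeline_config(),
                              enc = toy_encoder()) {
  stopifnot(length(fractions) > 0, all(fractions > 0), all(fractions <= 1))
  gold <- sentences_as_corpus(test_sentences)
  rows <- lapply(fractions, function(f) {
    cfg <- config
    cfg$training_fraction <- f
    res <- run_corpus(test_sentences, training_pool, backend, cfg, enc)
    r <- eval_row(evaluate(res$predictions, gold))
    tibble::tibble(fraction = f, n_sentences = res$n_pool, !!!as.list(r))
  })
  do.call(rbind, rows)
}

#' Ablation grid over modes and training fractions
#'
#' @param modes Subset of the four ablation arms.
#' @param fractions Training fractions, default 1.
#' @param test_sentences,training_pool,backend,config,enc See
#'   [run_corpus()].
#' @return A tibble with one row per (mode, fraction) cell.
#' @export
sweep_ablation <- function(modes, test_sentences, training_pool, backend,
                           config = pipeline_config(), enc = toy_encoder(),
                           fractions = 1) {
  stopifnot(all(modes %in% c("baseline", "baseline_sv", "baseline_cot",
                             "full")))
  gold <- sentences_as_corpus(test_sentences)
  grid <- expand.grid(mode = modes, fraction = fractions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$mode <- grid$mode[i]
    cfg$training_fraction <- grid$fraction[i]
    res <- run_corpus(test_sentences, training_pool, backend, cfg, enc)
    r <- eval_row(evaluate(res$predictions, gold))
    tibble::tibble(mode = grid$mode[i], fraction = grid$fraction[i],
                   n_sentences = res$n_pool, !!!as.list(r))
  })
  do.call(rbind, rows)
}

#' Wrap a flat sentence list as a corpus (for evaluation)
#'
#' Groups sentences by their `doc_id` into documents, preserving order.
#'
#' @param sentences List of `ms_sentence`.
#' @return An `ms_corpus`.
#' @export
sentences_as_corpus <- function(sentences) {
  doc_of <- vapply(sentences, function(s) s$doc_id, character(1))
  by_doc <- split(sentences, factor(doc_of, levels = unique(doc_of)))
  ms_corpus(lapply(names(by_doc), function(id)
    ms_document(id, sentences = by_doc[[id]])), validate = FALSE)
}
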