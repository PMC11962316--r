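# Uniform chat-completion contract: remote-adapter shape, response cache,
# retry policy, and a deterministic gold-playback oracle for offline runs.

#' LLM sampling configuration
#'
#' @param temperature Sampling temperature (default 0.02 — near-greedy
#'   decoding for reproducible extraction).
#' @param max_tokens Completion cap (default 2048).
#' @param model Model name string, passed through to adapters.
#' @param retries Number of attempts on transient backend failure.
#' @param retry_delay Seconds between attempts.
#' @return An object of class `ms_llm_config`.
#' @export
llm_config <- function(temperature = 0.02, max_tokens = 2048L,
                       model = "", retries = 3L, retry_delay = 0) {
  stopifnot(temperature >= 0, max_tokens >= 1, retries >= 1)
  structure(
    list(temperature = temperature, max_tokens = as.integer(max_tokens),
         model = model, retries = as.integer(retries),
         retry_delay = retry_delay),
    class = "ms_llm_config"
  )
}

new_backend <- function(id, subclass, fields = list()) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  env$cache <- new.env(parent = emptyenv())
  structure(c(list(id = id, env = env), fields),
            class = c(subclass, "ms_backend"))
}

#' Wrap a completion function as a backend
#'
#' The adapter contract: `fn(prompt_text, config)` returns the completion
#' text or signals an error. This is the shape a remote HTTP adapter plugs
#' into; the function receives only the rendered prompt text, never prompt
#' metadata.
#'
#' @param fn Completion function.
#' @param id Backend identity string (part of the cache key).
#' @return An `ms_backend`.
#' @export
fn_backend <- function(fn, id = "fn") {
  new_backend(id, "ms_fn_backend", list(fn = fn))
}

#' Gold-playback oracle backend
#'
#' A deterministic test double for a chat LLM. It answers the three prompt
#' kinds from the gold annotation of the corpus it was built on, after
#' applying the error-injection model of [perturb_gold()]: step 1 returns
#' the brace-list of entity types among the perturbed mentions (`{null}`
#' when none survive); step 2 returns the sentence with the perturbed
#' mentions marker-rendered (restricted to the types the prompt asked
#' for); step 3 answers "Yes" when the queried (surface, type) pair is a
#' gold mention of the sentence and "No" otherwise, additionally flipping a
#' correct "Yes" to "No" with probability `p_verify_no`. With all error
#' rates zero the full pipeline reproduces the gold annotation exactly.
#'
#' The sentence identity travels in prompt metadata, a structured side
#' channel the renderers fill in — the prompt text itself is identical to
#' what a real backend would receive.
#'
#' @param gold_corpus An `ms_corpus` with gold annotations.
#' @param ec An [error_config()] controlling injected errors.
#' @return An `ms_backend`.
#' @export
oracle_backend <- function(gold_corpus, ec = error_config()) {
  lookup <- new.env(parent = emptyenv())
  for (s in corpus_sentences(gold_corpus)) assign(s$sent_id, s, envir = lookup)
  b <- new_backend("oracle", "ms_oracle_backend",
                   list(ec = ec, lookup = lookup))
  b$env$perturbed <- new.env(parent = emptyenv())
  b
}

backend_call <- function(backend, prompt, config) UseMethod("backend_call")

#' @export
backend_call.ms_fn_backend <- function(backend, prompt, config) {
  backend$fn(prompt$text, config)
}

#' @export
backend_call.ms_oracle_backend <- function(backend, prompt, config) {
  oracle_complete(backend, prompt)
}

oracle_perturbed <- function(backend, sent) {
  cacheenv <- backend$env$perturbed
  if (!is.null(cacheenv[[sent$sent_id]])) return(cacheenv[[sent$sent_id]])
  p <- perturb_gold(sent, backend$ec)
  cacheenv[[sent$sent_id]] <- p
  p
}

#' Answer a prompt from gold annotations
#'
#' The response logic behind [oracle_backend()]; exposed for direct testing.
#'
#' @param backend An oracle backend.
#' @param prompt An `ms_prompt` whose metadata carries `step` and
#'   `sent_id`.
#' @return Response text.
#' @export
oracle_complete <- function(backend, prompt) {
  meta <- prompt$meta
  if (is.null(meta$sent_id)) {
    stop("oracle backend: prompt metadata lacks sent_id")
  }
  sent <- backend$lookup[[meta$sent_id]]
  if (is.null(sent)) stop("oracle backend: unknown sent_id ", meta$sent_id)
  perturbed <- oracle_perturbed(backend, sent)

  if (identical(meta$step, "type")) {
    types <- intersect(entity_types(),
                       unique(vapply(perturbed, function(m) m$etype,
                                     character(1))))
    if (length(types) == 0) return(NULL_TOKEN)
    return(paste0("{", paste(types, collapse = ", "), "}"))
  }

  if (identical(meta$step, "label")) {
    want <- meta$types %||% entity_types()
    ms <- Filter(function(m) m$etype %in% want && mention_anchored(m),
                 perturbed)
    return(render_marked(sent$text, ms))
  }

  if (identical(meta$step, "verify")) {
    in_gold <- any(vapply(sent$mentions, function(g)
      identical(g$surface, meta$surface) && identical(g$etype, meta$etype),
      logical(1)))
    if (!in_gold) return("No")
    if (backend$ec$p_verify_no > 0) {
      flip <- withr::with_seed(
        derive_seed(backend$ec$seed, "verify", meta$sent_id,
                    meta$surface, meta$etype),
        stats::runif(1) < backend$ec$p_verify_no)
      if (flip) return("No")
    }
    return("Yes")
  }

  stop("oracle backend: unknown prompt step '", meta$step %||% "?", "'")
}

cache_key <- function(backend, prompt, config) {
  paste(backend$id, str_hash(prompt$text), config$temperature,
        config$max_tokens, sep = ":")
}

#' Complete a prompt through a backend
#'
#' Single entry point for all LLM calls: consults the response cache (keyed
#' by backend identity, prompt text, temperature and max_tokens), retries
#' transient failures per the config's policy, counts raw backend
#' invocations, and optionally appends every call to a JSON-Lines audit
#' log.
#'
#' @param backend An `ms_backend`.
#' @param prompt An `ms_prompt`.
#' @param config An [llm_config()].
#' @param use_cache Serve repeat prompts from the cache (default `TRUE`;
#'   caching never changes outputs, only call counts).
#' @param log_file Optional path; each call is appended as a JSON line.
#' @return Response text.
#' @export
complete <- function(backend, prompt, config = llm_config(),
                     use_cache = TRUE, log_file = NULL) {
  stopifnot(inherits(backend, "ms_backend"), inherits(prompt, "ms_prompt"))
  key <- cache_key(backend, prompt, config)
  if (use_cache && !is.null(backend$env$cache[[key]])) {
    return(backend$env$cache[[key]])
  }
  last_err <- NULL
  resp <- NULL
  for (attempt in seq_len(config$retries)) {
    resp <- tryCatch({
      backend$env$calls <- backend$env$calls + 1L
      backend_call(backend, prompt, config)
    }, error = function(e) {
      last_err <<- e
      NULL
    })
    if (!is.null(resp)) break
    if (attempt < config$retries && config$retry_delay > 0) {
      Sys.sleep(config$retry_delay)
    }
  }
  if (is.null(resp)) {
    stop("backend '", backend$id, "' failed after ", config$retries,
         " attempts: ", conditionMessage(last_err))
  }
  if (use_cache) backend$env$cache[[key]] <- resp
  if (!is.null(log_file)) {
    rec <- jsonlite::toJSON(
      list(backend = backend$id, step = prompt$meta$step %||% NA,
           sent_id = prompt$meta$sent_id %||% NA,
           prompt_hash = str_hash(prompt$text), response = resp),
      auto_unbox = TRUE)
    cat(rec, "\n", sep = "", file = log_file, append = TRUE)
  }
  resp
}

#' Number of raw backend invocations so far
#'
#' Cache hits do not count. Useful for asserting call-count properties
#' (e.g. that an empty step-1 result short-circuits steps 2 and 3).
#'
#' @param backend An `ms_backend`.
#' @return Integer call count.
#' @export
backend_calls <- function(backend) backend$env$calls
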