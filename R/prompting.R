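# Prompt rendering for the three pipeline steps and parsing of LLM
# responses, including the marker grammar for labeled text.

# Marker grammar: [[type]]surface[[/type]]. Double square brackets are
# collision-resistant in Chinese prose and survive most LLM copy-through.
MARKER_OPEN <- function(etype) paste0("[[", etype, "]]")
MARKER_CLOSE <- function(etype) paste0("[[/", etype, "]]")
NULL_TOKEN <- "{null}"

ROLE_PREAMBLE <- paste(
  "You are a sophisticated linguist and named entity annotation expert",
  "for Chinese medical literature.")

#' Default entity definitions
#'
#' Per-type name, definition and possible-forms notes shown to the model in
#' every prompt. Editing these definitions is the supported way to adapt the
#' framework to new domains.
#'
#' @return Named list (one entry per entity type) with `name`, `definition`
#'   and `forms` fields.
#' @export
default_entity_definitions <- function() {
  list(
    scale = list(
      name = "scale",
      definition = paste(
        "The official or widely recognized title of a medical measurement",
        "scale, e.g. 焦虑自评量表(SAS)."),
      forms = paste(
        "May appear as a full Chinese title, an English title, an",
        "abbreviation in parentheses, or a title plus version or",
        "population qualifier.")
    ),
    concept = list(
      name = "concept",
      definition = paste(
        "The broader theoretical or clinical construct a scale is designed",
        "to assess, e.g. anxiety, sleep quality, cognitive function."),
      forms = "Usually a short noun phrase naming the measured construct."
    ),
    item = list(
      name = "item",
      definition = paste(
        "An individual question or statement within a scale that evaluates",
        "a specific aspect of the measurement concept."),
      forms = "Often a first-person statement or a short questionnaire entry."
    )
  )
}

render_definitions <- function(defs) {
  paste(vapply(defs, function(d) {
    paste0("- ", d$name, ": ", d$definition, " Forms: ", d$forms)
  }, character(1)), collapse = "\n")
}

new_prompt <- function(body, meta = list()) {
  structure(
    list(role = ROLE_PREAMBLE, body = body,
         text = paste(ROLE_PREAMBLE, body, sep = "\n\n"),
         meta = meta),
    class = "ms_prompt"
  )
}

#' Render the zero-shot entity-type recognition prompt (step 1)
#'
#' Four components in order: task description, entity definitions, output
#' format, input text. No demonstrations are included; the model is
#' instructed to answer with a brace-delimited list of the types present and
#' with `{null}` when the sentence contains none.
#'
#' @param defs Entity definitions, see [default_entity_definitions()].
#' @param sentence_text Input sentence.
#' @param sent_id Optional sentence id, carried in prompt metadata (a side
#'   channel used by the playback backend; real backends see only the
#'   prompt text).
#' @return An `ms_prompt`.
#' @export
render_type_prompt <- function(defs = default_entity_definitions(),
                               sentence_text = "", sent_id = NULL) {
  body <- paste0(
    "Task: identify which entity types are present in the input text. ",
    "List each type at most once, even if it occurs several times.\n\n",
    "Entity definitions:\n", render_definitions(defs), "\n\n",
    "Output format: a single brace-delimited list of type names, e.g. ",
    "{scale, concept}. Do not add explanations. If no entities are ",
    "present, return exactly ", NULL_TOKEN, ".\n\n",
    "Input text:\n", sentence_text
  )
  new_prompt(body, meta = list(step = "type", sent_id = sent_id))
}

#' Parse a step-1 type response
#'
#' Looks for the first brace-delimited group and matches its contents
#' against the type inventory case-insensitively; failing a brace group, any
#' inventory name occurring in the raw text counts. `{null}`, or no
#' recognizable type, yields the empty set.
#'
#' @param raw Raw LLM response text.
#' @return Character vector, a subset of [entity_types()] without
#'   duplicates (order follows the inventory).
#' @export
parse_type_response <- function(raw) {
  if (is.null(raw) || !nzchar(raw)) return(character(0))
  m <- regmatches(raw, regexpr("\\{[^}]*\\}", raw))
  hay <- if (length(m)) m else raw
  if (length(m) && grepl("^\\{\\s*null\\s*\\}$", m, ignore.case = TRUE)) {
    return(character(0))
  }
  found <- entity_types()[vapply(entity_types(), function(t)
    grepl(t, hay, ignore.case = TRUE), logical(1))]
  if (length(found) == 0 && length(m) == 0) {
    # no brace group and no type name anywhere
    return(character(0))
  }
  found
}

#' Render a sentence with its mentions wrapped in markers
#'
#' Each anchored mention is wrapped as `[[type]]surface[[/type]]`; all other
#' characters pass through unchanged, left to right. This is the labeled
#' output format demonstrated to, and expected from, the model in step 2.
#'
#' @param sentence_text Sentence text.
#' @param mentions Anchored, non-overlapping `ms_mention` list.
#' @return The marked string.
#' @export
render_marked <- function(sentence_text, mentions) {
  if (length(mentions) == 0) return(sentence_text)
  if (!all(vapply(mentions, mention_anchored, logical(1)))) {
    stop("render_marked: all mentions must be anchored")
  }
  ms <- mentions[order(vapply(mentions, function(m) m$start, integer(1)))]
  out <- character(0)
  cursor <- 0L
  len <- n_cp(sentence_text)
  for (m in ms) {
    if (m$start < cursor) stop("render_marked: overlapping mentions")
    if (m$end > len) stop("render_marked: mention exceeds sentence length")
    out <- c(out, substr_cp(sentence_text, cursor, m$start),
             MARKER_OPEN(m$etype), m$surface, MARKER_CLOSE(m$etype))
    cursor <- m$end
  }
  paste0(paste(out, collapse = ""), substr_cp(sentence_text, cursor, len))
}

#' Render the few-shot entity-labeling prompt (step 2)
#'
#' Components in order: task description, entity definitions,
#' demonstrations, output format, input sentence. Each demonstration is a
#' raw-sentence/marked-sentence pair. Demonstrations are emitted in
#' ascending similarity, so the most similar example sits adjacent to the
#' input sentence.
#'
#' @param defs Entity definitions.
#' @param demonstrations Ranked list from [retrieve()] (most similar
#'   first).
#' @param predicted_types Non-empty character vector of types to label.
#' @param sentence_text Input sentence.
#' @param sent_id Optional sentence id for prompt metadata.
#' @return An `ms_prompt`.
#' @export
render_label_prompt <- function(defs = default_entity_definitions(),
                                demonstrations = list(),
                                predicted_types = entity_types(),
                                sentence_text = "", sent_id = NULL) {
  stopifnot(length(predicted_types) > 0)
  demo_block <- if (length(demonstrations) == 0) "(no examples)" else {
    shown <- rev(demonstrations)  # ascending similarity
    paste(vapply(seq_along(shown), function(i) {
      d <- shown[[i]]
      paste0("Example ", i, ":\nInput: ", d$sentence$text,
             "\nOutput: ", d$marked_text)
    }, character(1)), collapse = "\n\n")
  }
  body <- paste0(
    "Task: label every entity of the following types in the input ",
    "sentence: {", paste(predicted_types, collapse = ", "), "}. ",
    "Reproduce the sentence and surround each entity with markers, ",
    "as in the examples.\n\n",
    "Entity definitions:\n", render_definitions(defs), "\n\n",
    "Examples:\n", demo_block, "\n\n",
    "Output format: the input sentence with every entity wrapped as ",
    "[[type]]entity[[/type]]. Return the sentence unchanged if it ",
    "contains no entities.\n\n",
    "Input sentence:\n", sentence_text
  )
  new_prompt(body, meta = list(step = "label", sent_id = sent_id,
                               types = predicted_types))
}

#' Parse a marked step-2 response into entity mentions
#'
#' Scans `raw` for balanced `[[type]]...[[/type]]` pairs. Offsets are
#' recovered positionally: the characters outside markers consumed before a
#' mention give its start offset, and when the original sentence confirms
#' the surface at that position the mention is anchored there. When the
#' model rewrote surrounding text, each surface falls back to a leftmost
#' exact search in the original sentence starting after the previous
#' anchor's start; surfaces not found anywhere are kept unanchored.
#' Unbalanced or unknown-type markers are skipped with a warning. The
#' parser never errors on arbitrary input — LLM output is untrusted.
#'
#' @param raw Raw LLM response.
#' @param original_sentence The sentence the model was asked to label.
#' @return List of `ms_mention` (possibly unanchored).
#' @export
parse_marked <- function(raw, original_sentence) {
  if (is.null(raw) || is.na(raw) || !nzchar(raw)) return(list())
  raw <- enc2utf8(raw)
  pat <- "\\[\\[(/?)([A-Za-z_]+)\\]\\]"
  toks <- gregexpr(pat, raw, perl = TRUE)[[1]]
  if (toks[1] == -1) return(list())
  tok_str <- regmatches(raw, gregexpr(pat, raw, perl = TRUE))[[1]]
  closing <- grepl("^\\[\\[/", tok_str)
  ttype <- sub(pat, "\\2", tok_str, perl = TRUE)
  tok_start <- as.integer(toks)                       # 1-based char pos
  tok_len <- attr(toks, "match.length")

  mentions <- list()
  consumed <- 0L   # original-text characters consumed outside markers
  cursor <- 1L     # position in raw (1-based, code points)
  search_from <- 1L
  i <- 1L
  n <- length(tok_str)
  orig_len <- n_cp(original_sentence)
  while (i <= n) {
    if (closing[i]) {  # stray closer
      warning("parse_marked: unbalanced closing marker [[/", ttype[i], "]]")
      consumed <- consumed + (tok_start[i] - cursor)
      cursor <- tok_start[i] + tok_len[i]
      i <- i + 1L
      next
    }
    consumed <- consumed + (tok_start[i] - cursor)
    open_end <- tok_start[i] + tok_len[i]
    # find the matching closer of the same type before any other marker
    if (i + 1L <= n && closing[i + 1L] && ttype[i + 1L] == ttype[i]) {
      surface <- substr(raw, open_end, tok_start[i + 1L] - 1L)
      if (!(ttype[i] %in% entity_types())) {
        warning("parse_marked: unknown entity type '", ttype[i], "'")
        consumed <- consumed + nchar(surface, type = "chars")
      } else if (!nzchar(surface)) {
        warning("parse_marked: empty mention skipped")
      } else {
        start0 <- consumed            # candidate 0-based offset
        end0 <- start0 + nchar(surface, type = "chars")
        if (end0 <= orig_len &&
            identical(substr_cp(original_sentence, start0, end0), surface)) {
          m <- entity_mention(surface, ttype[i], start0, end0)
          search_from <- start0 + 2L
        } else {
          hit <- find_from(original_sentence, surface, search_from)
          if (is.na(hit)) hit <- find_from(original_sentence, surface, 1L)
          if (is.na(hit)) {
            warning("parse_marked: surface '", surface,
                    "' not found in original sentence; kept unanchored")
            m <- entity_mention(surface, ttype[i])
          } else {
            m <- entity_mention(surface, ttype[i], hit - 1L,
                                hit - 1L + nchar(surface, type = "chars"))
            search_from <- hit + 1L
          }
        }
        mentions[[length(mentions) + 1L]] <- m
        consumed <- consumed + nchar(surface, type = "chars")
      }
      cursor <- tok_start[i + 1L] + tok_len[i + 1L]
      i <- i + 2L
    } else {
      warning("parse_marked: unclosed marker [[", ttype[i], "]]")
      cursor <- open_end
      i <- i + 1L
    }
  }
  mentions
}

# 1-based position of first occurrence of needle in haystack at or after
# `from` (1-based), NA if none. Operates on code points.
find_from <- function(haystack, needle, from) {
  hs <- enc2utf8(haystack)
  len <- n_cp(hs)
  if (from > len) return(NA_integer_)
  tail <- substr(hs, from, len)
  hit <- regexpr(needle, tail, fixed = TRUE)
  if (hit == -1) return(NA_integer_)
  from + as.integer(hit) - 1L
}

#' Render the self-verification prompt (step 3)
#'
#' Shows the candidate entity with its full sentence context and asks for a
#' bare Yes/No answer on whether it is a correct entity of its type,
#' preceded by optional few-shot verification examples (question/answer
#' pairs).
#'
#' @param mention The `ms_mention` to verify.
#' @param sentence_text Sentence containing the mention.
#' @param examples List of `list(mention =, sentence =, verdict =)` few-shot
#'   cases, with `verdict` `"Yes"` or `"No"`.
#' @param sent_id Optional sentence id for prompt metadata.
#' @return An `ms_prompt`.
#' @export
render_verify_prompt <- function(mention, sentence_text, examples = list(),
                                 sent_id = NULL) {
  render_q <- function(m, stext) {
    paste0("Sentence: ", stext, "\nIs \"", m$surface,
           "\" a correct entity of type \"", m$etype,
           "\" in this sentence? Answer Yes or No.")
  }
  ex_block <- if (length(examples) == 0) "" else paste0(
    "Examples:\n",
    paste(vapply(examples, function(e)
      paste0(render_q(e$mention, e$sentence), "\nAnswer: ", e$verdict),
      character(1)), collapse = "\n\n"),
    "\n\n")
  body <- paste0(
    "Task: verify a labeled entity. Answer with a single word, Yes or ",
    "No.\n\n", ex_block, render_q(mention, sentence_text)
  )
  new_prompt(body, meta = list(step = "verify", sent_id = sent_id,
                               surface = mention$surface,
                               etype = mention$etype))
}

#' Parse a Yes/No verification response
#'
#' The first standalone "yes"/"no" token (case-insensitive; the Chinese
#' single-character equivalents are also accepted) decides. A response with
#' neither defaults to "yes" with a warning: an entity is only removed on an
#' explicit No.
#'
#' @param raw Raw LLM response.
#' @return List with `decision` (`"yes"` or `"no"`) and `raw_text`.
#' @export
parse_verify_response <- function(raw) {
  if (is.null(raw) || is.na(raw)) raw <- ""
  m <- regmatches(raw, regexpr("(?i)(?<![a-z])(yes|no)(?![a-z])|[是否]",
                               raw, perl = TRUE))
  decision <- if (length(m) == 0) {
    warning("parse_verify_response: no Yes/No found; defaulting to yes")
    "yes"
  } else {
    tok <- tolower(m)
    if (tok %in% c("yes", "是")) "yes" else "no"
  }
  list(decision = decision, raw_text = raw)
}
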