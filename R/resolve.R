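# Term resolution: mapping free-text input onto ontology terms through
# tiered matching, term-form linting, new-term proposals and duplicate
# detection. Matching is exact-after-normalization; there is no fuzzy
# matching, so results are deterministic and auditable.

#' Normalize a label to its canonical stored form
#'
#' Lowercases, trims, collapses internal whitespace and unifies spaces,
#' hyphens and underscores to a single underscore. Idempotent.
#'
#' @param s Character vector of labels.
#' @return Character vector of canonical labels.
#' @export
normalize_label <- function(s) {
  s <- tolower(trimws(s))
  s <- gsub("[ \t_-]+", "_", s)
  gsub("^_+|_+$", "", s)
}

#' Display form of a canonical label
#' @param s Canonical (underscore) label.
#' @return Label with underscores replaced by spaces.
#' @export
display_label <- function(s) gsub("_", " ", s)

match_tiers <- c("exact_label", "exact_synonym", "broad_synonym",
                 "not_recommended_synonym", "deprecated_replaced", "none")

new_match_result <- function(query, matched_term = NULL, match_kind = "none",
                             suggestion = NULL, warnings = character(0)) {
  structure(list(query = query, matched_term = matched_term,
                 match_kind = match_kind, suggestion = suggestion,
                 warnings = warnings),
            class = "charrec_match")
}

#' Match free-text input against the ontology
#'
#' Matching proceeds in strict tier priority: exact canonical label,
#' exact synonym, broad synonym, not-recommended synonym — all over live
#' terms — and finally label or exact synonym of a deprecated term, in
#' which case the suggestion is the live end of its replacement chain.
#' Ties within a tier are broken by ascending `TermId`. Unmatched input
#' returns `match_kind = "none"` (callers may then propose a new term).
#'
#' @param o A `carex_ontology`.
#' @param query Free-text input.
#' @return A `charrec_match` with fields `query`, `matched_term`,
#'   `match_kind`, `suggestion`, `warnings`.
#' @export
match_term <- function(o, query) {
  q <- normalize_label(query)
  if (!nzchar(q)) return(new_match_result(query))
  ids <- names(o$terms)
  ids <- ids[order(ids)]
  live <- ids[!vapply(ids, function(i) o$terms[[i]]$deprecated, logical(1))]
  dead <- setdiff(ids, live)
  hit_in <- function(cands, field) {
    for (id in cands) {
      t <- o$terms[[id]]
      strings <- if (field == "label") t$label else t[[field]]
      if (q %in% normalize_label(strings)) return(id)
    }
    NULL
  }
  id <- hit_in(live, "label")
  if (!is.null(id)) {
    return(new_match_result(query, id, "exact_label"))
  }
  id <- hit_in(live, "exact_synonyms")
  if (!is.null(id)) {
    return(new_match_result(query, id, "exact_synonym", suggestion = id))
  }
  id <- hit_in(live, "broad_synonyms")
  if (!is.null(id)) {
    t <- o$terms[[id]]
    return(new_match_result(query, id, "broad_synonym", suggestion = id,
      warnings = sprintf(
        "'%s' is a broad synonym of '%s': only one sense of the input matches",
        query, t$label)))
  }
  id <- hit_in(live, "not_recommended_synonyms")
  if (!is.null(id)) {
    t <- o$terms[[id]]
    return(new_match_result(query, id, "not_recommended_synonym", suggestion = id,
      warnings = sprintf("'%s' is discouraged; preferred term is '%s'",
                         query, t$label)))
  }
  for (field in c("label", "exact_synonyms")) {
    id <- hit_in(dead, field)
    if (!is.null(id)) {
      sugg <- tryCatch(resolve_replacement_chain(o, id), charrec_error = function(e) NULL)
      if (is.null(sugg)) {
        return(new_match_result(query, warnings = sprintf(
          "'%s' matches deprecated term %s which has no live replacement", query, id)))
      }
      return(new_match_result(query, id, "deprecated_replaced", suggestion = sugg,
        warnings = sprintf("'%s' is deprecated in favor of '%s'",
                           o$terms[[id]]$label, o$terms[[sugg]]$label)))
    }
  }
  new_match_result(query)
}

# ---- term-form linting ------------------------------------------------------

default_form_config <- function() {
  path <- system.file("extdata", "config", "term_form.json", package = "charrec")
  if (nzchar(path)) jsonlite::read_json(path, simplifyVector = TRUE) else
    list(prepositions = c("in", "on", "at", "of", "with", "under", "over",
                          "along", "between"),
         conjunctions = c("and", "or", "and/or"),
         plural_exceptions = character(0),
         singular_suffixes = c("ous", "us", "is", "ss"))
}

#' Lint the form of a candidate term label
#'
#' Flags the error patterns observed in user-contributed terms: labels
#' beginning with a preposition, labels embedding a conjunction
#' (`and`, `or`, `and/or`), and plural head nouns (suffix heuristic with
#' an exception lexicon). Flags are warnings for the curation queue,
#' never hard rejections. The stop-lists live in a JSON config file so
#' they can grow without code changes.
#'
#' @param s Candidate label (display or canonical form).
#' @param config Optional config list overriding the packaged defaults.
#' @return A list with element `flags`: a list of `list(kind, span)`
#'   records, empty for a well-formed singular noun phrase.
#' @export
validate_term_form <- function(s, config = default_form_config()) {
  tokens <- strsplit(trimws(tolower(gsub("[_]+", " ", s))), "[ \t]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  flags <- list()
  if (length(tokens)) {
    if (tokens[[1L]] %in% config$prepositions) {
      flags[[length(flags) + 1L]] <- list(kind = "leading_preposition",
                                          span = tokens[[1L]])
    }
    conj <- intersect(tokens, config$conjunctions)
    if (length(conj)) {
      flags[[length(flags) + 1L]] <- list(kind = "embedded_conjunction",
                                          span = conj[[1L]])
    }
    head_noun <- tokens[[length(tokens)]]
    if (is_plural_form(head_noun, config)) {
      flags[[length(flags) + 1L]] <- list(kind = "plural_form", span = head_noun)
    }
  }
  list(flags = flags)
}

is_plural_form <- function(word, config = default_form_config()) {
  if (word %in% config$plural_exceptions) return(FALSE)
  for (suf in config$singular_suffixes) {
    if (endsWith(word, suf)) return(FALSE)
  }
  endsWith(word, "s")
}

#' Propose a new term from unmatched user input
#'
#' Precondition: [match_term()] returned no match for the label. The term
#' is minted immediately (usable in matrices at once) and a
#' `new_term_approval` issue is enqueued for expert review, carrying the
#' term-form lint report; a missing definition is flagged on the issue.
#'
#' @param o A `carex_ontology`.
#' @param label Proposed label.
#' @param definition Optional definition text.
#' @param contributor User identifier.
#' @param queue An issue queue from [new_issue_queue()].
#' @return A list with `ontology`, `term`, `queue` and `issue_id`.
#' @export
propose_new_term <- function(o, label, definition = NULL, contributor = NULL,
                             queue = new_issue_queue()) {
  m <- match_term(o, label)
  if (m$match_kind != "none") {
    stop_charrec(sprintf("'%s' already resolves to %s (%s)", label,
                         m$matched_term, m$match_kind),
                 class = "duplicate", data = list(existing = m$matched_term))
  }
  res <- add_term(o, label, definition, contributor)
  report <- validate_term_form(label)
  form_flags <- vapply(report$flags, function(f) f$kind, character(1))
  if (is.null(definition) || !nzchar(trimws(definition %||% ""))) {
    form_flags <- c(form_flags, "missing_definition")
  }
  q <- enqueue_issue(queue, res$ontology, type = "new_term_approval",
                     terms = res$term$id, proposed_text = res$term$label,
                     contributor = contributor, form_flags = form_flags)
  list(ontology = res$ontology, term = res$term, queue = q$queue,
       issue_id = q$id)
}

default_equivalence_lexicon <- function() {
  path <- system.file("extdata", "config", "equivalence_lexicon.json",
                      package = "charrec")
  if (nzchar(path)) {
    lapply(jsonlite::read_json(path), function(g) unlist(g, use.names = FALSE))
  } else {
    list(c("below", "beneath"), c("caespitose", "cespitose"))
  }
}

#' Detect candidate equivalent-term pairs
#'
#' Returns unordered pairs of live terms whose normalized labels are
#' equal, that share an exact synonym string, or whose labels fall in the
#' same group of the equivalence lexicon (packaged default includes
#' below/beneath). Each pair can be enqueued once as an
#' `equivalent_term_determination` issue when a queue is supplied.
#'
#' @param o A `carex_ontology`.
#' @param lexicon List of character vectors, each an equivalence group.
#' @param queue Optional issue queue; pairs are enqueued (coalesced).
#' @return A list with `pairs` (data frame with columns `a`, `b`,
#'   `reason`) and, when a queue was given, the updated `queue`.
#' @export
detect_equivalent_candidates <- function(o, lexicon = default_equivalence_lexicon(),
                                         queue = NULL) {
  live <- Filter(function(t) !t$deprecated, o$terms)
  ids <- vapply(live, function(t) t$id, character(1))
  ids <- sort(unname(ids))
  canon <- function(label) {
    lab <- normalize_label(label)
    for (group in lexicon) {
      g <- normalize_label(group)
      if (lab %in% g) return(sort(g)[[1L]])
    }
    lab
  }
  rows <- list()
  seen <- character(0)
  add_pair <- function(a, b, reason) {
    p <- sort(c(a, b))
    key <- paste(p, collapse = "|")
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    rows[[length(rows) + 1L]] <<- data.frame(a = p[[1L]], b = p[[2L]],
                                             reason = reason,
                                             stringsAsFactors = FALSE)
  }
  n <- length(ids)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        ti <- o$terms[[ids[[i]]]]; tj <- o$terms[[ids[[j]]]]
        if (normalize_label(ti$label) == normalize_label(tj$label)) {
          add_pair(ti$id, tj$id, "equal_label")
        } else if (length(intersect(normalize_label(ti$exact_synonyms),
                                    normalize_label(tj$exact_synonyms)))) {
          add_pair(ti$id, tj$id, "shared_exact_synonym")
        } else if (canon(ti$label) == canon(tj$label)) {
          add_pair(ti$id, tj$id, "equivalence_lexicon")
        }
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(0), b = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  out <- list(pairs = pairs)
  if (!is.null(queue)) {
    for (i in seq_len(nrow(pairs))) {
      q <- enqueue_issue(queue, o, type = "equivalent_term_determination",
                         terms = c(pairs$a[[i]], pairs$b[[i]]),
                         proposed_text = pairs$reason[[i]])
      queue <- q$queue
    }
    out$queue <- queue
  }
  out
}
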