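# The taxon-by-character matrix: state recording with modifiers,
# constraints and colors; shared-value pools for reuse across users;
# deprecation update flags; and matrix quality metrics. All operations
# are functional; timestamps come from an injectable clock so sessions
# are reproducible.

#' Create an empty matrix session
#'
#' @param registry A `chr_registry` defining the recordable characters.
#' @param clock A zero-argument function returning an ISO-8601 UTC
#'   timestamp string; defaults to the system clock. Fixtures inject a
#'   deterministic counter clock.
#' @return An object of class `cr_matrix`.
#' @export
new_matrix <- function(registry, clock = NULL) {
  structure(list(
    registry = registry,
    cells = list(),
    pool = list(),
    flags = list(),
    next_flag = 1L,
    clock = clock %||% function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC")
  ), class = "cr_matrix")
}

cell_key <- function(taxon, sample, character) {
  paste(taxon, sample, character, sep = "\r")
}

state_value_key <- function(st) {
  switch(st$kind,
    term = paste0("term:", st$term),
    range = sprintf("range:%g:%g:%s", st$low, st$high, st$unit),
    color = sprintf("color:%s:%s", st$color$label,
                    paste(st$color$srgb %||% "", collapse = ",")),
    raw = paste0("raw:", st$raw)
  )
}

state_display <- function(o, st) {
  val <- switch(st$kind,
    term = display_label(get_term(o, st$term)$label),
    range = {
      unit_lab <- display_label(get_term(o, st$unit)$label)
      if (st$low == st$high) sprintf("%g %s", st$low, unit_lab)
      else sprintf("%g–%g %s", st$low, st$high, unit_lab)
    },
    color = if (identical(st$color$source, "palette"))
      sprintf("%s [rgb(%d,%d,%d)]", st$color$label, st$color$srgb[[1L]],
              st$color$srgb[[2L]], st$color$srgb[[3L]])
    else st$color$label,
    raw = st$raw
  )
  parts <- c(st$pre_constraint,
             if (!is.null(st$degree)) display_label(get_term(o, st$degree)$label),
             val,
             st$post_constraint,
             if (!is.null(st$certainty))
               sprintf("(%s)", display_label(get_term(o, st$certainty)$label)))
  paste(parts[nzchar(parts %||% "")], collapse = " ")
}

#' Record a character state in a matrix cell
#'
#' Free-text input is routed through [match_term()]; when the match is a
#' synonym, a discouraged form, or a deprecated term, the preferred term
#' is substituted (the raw input is always preserved in provenance).
#' Unmatched text is stored as a raw state pending a term proposal.
#' Numerical characters accept a single value or a `{low, high}` range in
#' the character's unit; categorical characters additionally accept
#' palette colors. Every recorded state is appended to the matrix's
#' shared-value pool for reuse by other users.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @param taxon,sample Row identifiers.
#' @param character Character id (`chr:` CURIE) defined in the registry.
#' @param input A character string (term text), a number, a
#'   `list(low=, high=)`, or a `color_value` from [pick_color()].
#' @param certainty,degree Optional modifier `TermId`s.
#' @param pre,post Optional free-text constraints.
#' @param user User identifier for provenance.
#' @param accept_suggestion Apply preferred-term substitution for
#'   not-recommended and deprecated matches (default `TRUE`).
#' @return The updated `cr_matrix`; the new state carries any resolution
#'   warnings in its `warnings` field.
#' @export
set_state <- function(m, o, taxon, sample, character, input,
                      certainty = NULL, degree = NULL,
                      pre = NULL, post = NULL, user = "anonymous",
                      accept_suggestion = TRUE) {
  ch <- m$registry$characters[[character]]
  if (is.null(ch)) {
    stop_charrec(sprintf("character '%s' is not defined in this matrix", character),
                 class = "not_found", data = list(character = character))
  }
  warnings <- character(0)
  raw_text <- NULL
  if (inherits(input, "color_value")) {
    if (ch$kind != "categorical") {
      stop_charrec("color input on a numerical character", class = "kind_mismatch")
    }
    st <- list(kind = "color", color = unclass(input))
    raw_text <- input$label
  } else if (is.numeric(input) || (is.list(input) && !is.null(input$low))) {
    if (ch$kind != "numerical") {
      stop_charrec(sprintf("numeric input for categorical character %s", character),
                   class = "kind_mismatch")
    }
    low <- if (is.list(input)) input$low else input
    high <- if (is.list(input)) (input$high %||% input$low) else input
    if (low > high) {
      stop_charrec(sprintf("invalid range: low (%g) > high (%g)", low, high),
                   class = "validation")
    }
    st <- list(kind = "range", low = low, high = high, unit = ch$unit)
    raw_text <- if (low == high) as.character(low) else sprintf("%g-%g", low, high)
  } else if (is.character(input) && length(input) == 1L) {
    if (ch$kind == "numerical") {
      stop_charrec(sprintf("text input for numerical character %s", character),
                   class = "kind_mismatch")
    }
    raw_text <- input
    res <- match_term(o, input)
    warnings <- res$warnings
    if (res$match_kind == "none") {
      st <- list(kind = "raw", raw = input, pending_term = TRUE)
      warnings <- c(warnings, sprintf(
        "'%s' is not in the ontology; consider proposing it as a new term", input))
    } else if (res$match_kind %in% c("not_recommended_synonym", "deprecated_replaced") &&
               accept_suggestion) {
      st <- list(kind = "term", term = res$suggestion)
    } else {
      st <- list(kind = "term", term = res$matched_term)
    }
  } else {
    stop_charrec("unsupported input type", class = "validation")
  }
  st$certainty <- certainty
  st$degree <- degree
  st$pre_constraint <- pre
  st$post_constraint <- post
  st$warnings <- warnings
  st$provenance <- list(list(user = user, time = m$clock(), raw = raw_text,
                             action = "record"))

  key <- cell_key(taxon, sample, character)
  cell <- m$cells[[key]] %||% list(taxon = taxon, sample = sample,
                                   character = character, states = list())
  cell$states[[length(cell$states) + 1L]] <- st
  m$cells[[key]] <- cell

  # shared-value pool
  pkey <- paste(taxon, character, sep = "\r")
  entries <- m$pool[[pkey]] %||% list()
  vkey <- state_value_key(st)
  found <- FALSE
  for (i in seq_along(entries)) {
    if (entries[[i]]$value_key == vkey) {
      entries[[i]]$count <- entries[[i]]$count + 1L
      entries[[i]]$contributors <- union(entries[[i]]$contributors, user)
      entries[[i]]$last_time <- st$provenance[[1L]]$time
      entries[[i]]$warnings <- union(entries[[i]]$warnings, warnings)
      found <- TRUE
      break
    }
  }
  if (!found) {
    entries[[length(entries) + 1L]] <- list(
      value_key = vkey, display = state_display(o, st), count = 1L,
      contributors = user, last_time = st$provenance[[1L]]$time,
      warnings = warnings)
  }
  m$pool[[pkey]] <- entries
  m
}

#' Previously recorded values for a taxon/character pair
#'
#' Entries are offered for reuse sorted by count (descending) then
#' recency; no auto-filtering is applied — a much-reused misspelling is
#' still offered, with its resolution warnings attached.
#'
#' @param m A `cr_matrix`.
#' @param taxon,character Pool key.
#' @return A data frame with columns `display`, `count`, `contributors`,
#'   `last_time`, `warnings` (empty if nothing recorded).
#' @export
get_shared_values <- function(m, taxon, character) {
  entries <- m$pool[[paste(taxon, character, sep = "\r")]] %||% list()
  if (!length(entries)) {
    return(data.frame(display = character(0), count = integer(0),
                      contributors = character(0), last_time = character(0),
                      warnings = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(entries, function(e) data.frame(
    display = e$display, count = e$count,
    contributors = paste(sort(e$contributors), collapse = ";"),
    last_time = e$last_time,
    warnings = paste(e$warnings, collapse = "; "),
    stringsAsFactors = FALSE)))
  df[order(df$count, df$last_time, decreasing = TRUE, method = "radix"), ,
     drop = FALSE]
}

#' Scan a matrix for states using deprecated terms
#'
#' One open flag is raised per (cell, state) whose term value is
#' deprecated; rescanning is idempotent — existing flags for the same
#' state are not duplicated. If the term's replacement chain cannot be
#' resolved, the flag is created without a suggestion and carries an
#' error note.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @return The updated matrix, with flags in `$flags`; open flags are
#'   summarized by [open_flags()].
#' @export
scan_deprecated <- function(m, o) {
  existing <- vapply(m$flags, function(f)
    paste(f$cell_key, f$state, f$old, sep = "\r"), character(1))
  for (key in names(m$cells)) {
    cell <- m$cells[[key]]
    for (si in seq_along(cell$states)) {
      st <- cell$states[[si]]
      if (!identical(st$kind, "term")) next
      t <- o$terms[[st$term]]
      if (is.null(t) || !t$deprecated) next
      fkey <- paste(key, si, st$term, sep = "\r")
      if (fkey %in% existing) next
      suggested <- tryCatch(resolve_replacement_chain(o, st$term),
                            charrec_error = function(e) NULL)
      fid <- sprintf("flag-%04d", m$next_flag)
      m$flags[[fid]] <- list(
        id = fid, kind = "deprecated_term", cell_key = key, state = si,
        old = st$term, suggested = suggested, status = "open",
        note = if (is.null(suggested)) "replacement chain unresolved")
      m$next_flag <- m$next_flag + 1L
      existing <- c(existing, fkey)
    }
  }
  m
}

#' Open update flags of a matrix
#' @param m A `cr_matrix`.
#' @return Data frame of open flags (id, taxon, sample, character, old,
#'   suggested).
#' @export
open_flags <- function(m) {
  open <- Filter(function(f) f$status == "open", m$flags)
  if (!length(open)) {
    return(data.frame(id = character(0), taxon = character(0),
                      sample = character(0), character = character(0),
                      old = character(0), suggested = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(open, function(f) {
    cell <- m$cells[[f$cell_key]]
    data.frame(id = f$id, taxon = cell$taxon, sample = cell$sample,
               character = cell$character, old = f$old,
               suggested = f$suggested %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Accept the suggested replacement for a deprecation flag
#'
#' Swaps the cell's value to the suggested live term, closes the flag,
#' and appends a swap record to the state's provenance (raw input
#' history is never erased).
#'
#' @param m A `cr_matrix`.
#' @param flag_id Flag identifier from [open_flags()].
#' @param user User identifier for provenance.
#' @return The updated matrix.
#' @export
accept_replacement <- function(m, flag_id, user = "anonymous") {
  f <- m$flags[[flag_id]]
  if (is.null(f)) stop_charrec(sprintf("unknown flag '%s'", flag_id), class = "not_found")
  if (f$status != "open") {
    stop_charrec(sprintf("flag %s is already %s", flag_id, f$status), class = "state")
  }
  if (is.null(f$suggested)) {
    stop_charrec(sprintf("flag %s has no suggested replacement", flag_id),
                 class = "state")
  }
  st <- m$cells[[f$cell_key]]$states[[f$state]]
  st$term <- f$suggested
  st$provenance[[length(st$provenance) + 1L]] <-
    list(user = user, time = m$clock(), raw = f$old,
         action = sprintf("replaced %s by %s", f$old, f$suggested))
  m$cells[[f$cell_key]]$states[[f$state]] <- st
  m$flags[[flag_id]]$status <- "accepted"
  m
}

#' Contest a term deprecation from a matrix flag
#'
#' The flag becomes `contested`, the recorded value is left unchanged,
#' and a `deprecation_dispute` issue is enqueued for expert review.
#'
#' @param m A `cr_matrix`.
#' @param flag_id Flag identifier.
#' @param rationale Free-text rationale for the dispute.
#' @param o A `carex_ontology`.
#' @param queue An issue queue.
#' @param user User identifier.
#' @return List with `matrix`, `queue` and `issue_id`.
#' @export
contest_deprecation <- function(m, flag_id, rationale, o,
                                queue = new_issue_queue(), user = "anonymous") {
  f <- m$flags[[flag_id]]
  if (is.null(f)) stop_charrec(sprintf("unknown flag '%s'", flag_id), class = "not_found")
  if (f$status != "open") {
    stop_charrec(sprintf("flag %s is already %s", flag_id, f$status), class = "state")
  }
  m$flags[[flag_id]]$status <- "contested"
  q <- enqueue_issue(queue, o, type = "deprecation_dispute", terms = f$old,
                     proposed_text = rationale, contributor = user)
  list(matrix = m, queue = q$queue, issue_id = q$id)
}

withdraw_flags_for_term <- function(m, term) {
  for (fid in names(m$flags)) {
    f <- m$flags[[fid]]
    if (f$old == term && f$status %in% c("open", "contested")) {
      m$flags[[fid]]$status <- "withdrawn"
    }
  }
  m
}

# ---- metrics ----------------------------------------------------------------

tokenize_words <- function(x) {
  toks <- unlist(strsplit(tolower(x), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

matrix_word_tokens <- function(m, o) {
  out <- character(0)
  for (cell in m$cells) {
    for (st in cell$states) {
      out <- c(out, tokenize_words(state_display(o, st)))
      for (f in c("pre_constraint", "post_constraint")) {
        if (!is.null(st[[f]])) out <- c(out, tokenize_words(st[[f]]))
      }
    }
  }
  out
}

#' Vocabulary variation across matrices
#'
#' Counts the distinct normalized word tokens (split on
#' non-alphanumerics, lowercased, numbers kept) across all state values
#' and constraints of the pooled matrices, and optionally the percent
#' reduction relative to a baseline vocabulary size:
#' `(1 - distinct/baseline) * 100`, rounded to the nearest integer.
#' The result is invariant under cell and matrix ordering.
#'
#' @param matrices A list of `cr_matrix` objects (pooled).
#' @param o A `carex_ontology` (used to render term values).
#' @param baseline Optional baseline distinct-word count to compare
#'   against (e.g. the vocabulary of freehand matrices for the same
#'   task).
#' @return List with `distinct_words`, `words` (sorted) and, when a
#'   baseline is given, `reduction_pct`.
#' @export
vocabulary_variation <- function(matrices, o, baseline = NULL) {
  if (inherits(matrices, "cr_matrix")) matrices <- list(matrices)
  words <- sort(unique(unlist(lapply(matrices, matrix_word_tokens, o = o))))
  out <- list(distinct_words = length(words), words = words)
  if (!is.null(baseline)) {
    if (baseline == 0) {
      stop_charrec("baseline vocabulary size is zero; reduction undefined",
                   class = "domain")
    }
    out$reduction_pct <- round((1 - length(words) / baseline) * 100)
  }
  out
}

#' Percent vocabulary reduction between two vocabulary sizes
#' @param baseline Distinct-word count of the baseline matrices.
#' @param observed Distinct-word count of the controlled matrices.
#' @return `(1 - observed/baseline) * 100`, rounded to nearest integer.
#' @export
vocabulary_reduction <- function(baseline, observed) {
  if (baseline == 0) {
    stop_charrec("baseline vocabulary size is zero; reduction undefined",
                 class = "domain")
  }
  round((1 - observed / baseline) * 100)
}

#' Check a matrix against the expected task sheet
#'
#' @param m A `cr_matrix`.
#' @param expected A list with counts `characters`, `samples`, `states`
#'   and optionally `cells`, a data frame with columns `taxon`, `sample`,
#'   `character`, `n_states` enumerating the task sheet. Omissions are
#'   reported per expected cell when the sheet is given, otherwise as
#'   count shortfalls.
#' @return List with counts `characters`, `samples`, `states`, a
#'   character vector `omissions`, and `complete` (no omissions).
#' @export
completeness_check <- function(m, expected) {
  chars <- unique(vapply(m$cells, function(c) c$character, character(1)))
  samples <- unique(vapply(m$cells, function(c) c$sample, character(1)))
  n_states <- sum(vapply(m$cells, function(c) length(c$states), integer(1)))
  omissions <- character(0)
  if (!is.null(expected$cells)) {
    sheet <- expected$cells
    for (i in seq_len(nrow(sheet))) {
      key <- cell_key(sheet$taxon[[i]], sheet$sample[[i]], sheet$character[[i]])
      have <- length((m$cells[[key]] %||% list(states = list()))$states)
      want <- sheet$n_states[[i]]
      if (have < want) {
        omissions <- c(omissions, sprintf(
          "%s / sample %s / %s: %d of %d state(s) recorded",
          sheet$taxon[[i]], sheet$sample[[i]], sheet$character[[i]], have, want))
      }
    }
  } else {
    if (length(chars) < (expected$characters %||% 0)) {
      omissions <- c(omissions, sprintf("characters: %d of %d",
                                        length(chars), expected$characters))
    }
    if (length(samples) < (expected$samples %||% 0)) {
      omissions <- c(omissions, sprintf("samples: %d of %d",
                                        length(samples), expected$samples))
    }
    if (n_states < (expected$states %||% 0)) {
      omissions <- c(omissions, sprintf("states: %d of %d", n_states,
                                        expected$states))
    }
  }
  list(characters = length(chars), samples = length(samples),
       states = n_states, omissions = omissions,
       complete = length(omissions) == 0L)
}

#' @export
print.cr_matrix <- function(x, ...) {
  n_states <- sum(vapply(x$cells, function(c) length(c$states), integer(1)))
  cat(sprintf("<cr_matrix> %d filled cell(s), %d state(s), %d flag(s)\n",
              length(x$cells), n_states, length(x$flags)))
  invisible(x)
}

# ---- session persistence ----------------------------------------------------

#' Save a matrix session to JSON
#'
#' The session file is the store of record; CSV/TriG/text are exports.
#' The clock is not serialized — re-inject one on load.
#'
#' @param m A `cr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(m, path) {
  payload <- list(
    schema = "charrec-session/1",
    cells = lapply(unname(m$cells), function(cell) {
      cell$states <- lapply(cell$states, function(st) {
        st$warnings <- as.list(st$warnings %||% character(0))
        st
      })
      cell
    }),
    pool = lapply(names(m$pool), function(k) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      list(taxon = parts[[1L]], character = parts[[2L]],
           entries = lapply(m$pool[[k]], function(e) {
             e$contributors <- as.list(e$contributors)
             e$warnings <- as.list(e$warnings)
             e
           }))
    }),
    flags = unname(m$flags),
    next_flag = m$next_flag
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a matrix session from JSON
#' @param path Session file from [save_matrix()].
#' @param registry The `chr_registry` the session was recorded against.
#' @param clock Optional clock to re-inject.
#' @return A `cr_matrix`.
#' @export
load_matrix <- function(path, registry, clock = NULL) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "charrec-session/1")) {
    stop_charrec(sprintf("%s: unknown session schema '%s'", path,
                         payload$schema %||% "<none>"), class = "format")
  }
  m <- new_matrix(registry, clock)
  for (cell in payload$cells) {
    cell$states <- lapply(cell$states, function(st) {
      st$warnings <- unlist(st$warnings) %||% character(0)
      if (!is.null(st$color)) st$color$srgb <- unlist(st$color$srgb)
      st
    })
    m$cells[[cell_key(cell$taxon, cell$sample, cell$character)]] <- cell
  }
  for (p in payload$pool) {
    m$pool[[paste(p$taxon, p$character, sep = "\r")]] <-
      lapply(p$entries, function(e) {
        e$contributors <- unlist(e$contributors)
        e$warnings <- unlist(e$warnings) %||% character(0)
        e
      })
  }
  for (f in payload$flags) m$flags[[f$id]] <- f
  m$next_flag <- payload$next_flag %||% (length(m$flags) + 1L)
  m
}
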