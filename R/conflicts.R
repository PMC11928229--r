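# The conflict-resolution queue: typed ontology issues raised during
# authoring (new terms, duplicates, category disputes, deprecation
# challenges), expert resolutions, and the application of resolutions to
# the ontology with update notices back to matrices. The queue is a
# total log: every ontology mutation outside fixture authoring traces to
# a resolved issue.

.issue_types <- c("category_assignment", "definition_approval",
                  "new_term_approval", "exact_synonym_identification",
                  "equivalent_term_determination", "deprecation_dispute",
                  "extension_type")

.resolution_actions <- c("assign_superclass", "approve_definition",
                         "approve_term", "merge_as_synonym",
                         "deprecate_with_replacement", "uphold_deprecation",
                         "revoke_deprecation", "reject")

# Which actions may resolve which issue type. The seventh type is a
# configurable extension slot with a documented schema: its semantics are
# supplied by deployment configuration, so it accepts the generic
# approve/reject actions only.
.type_actions <- list(
  category_assignment = c("assign_superclass", "reject"),
  definition_approval = c("approve_definition", "reject"),
  new_term_approval = c("approve_term", "assign_superclass",
                        "merge_as_synonym", "deprecate_with_replacement",
                        "reject"),
  exact_synonym_identification = c("merge_as_synonym", "reject"),
  equivalent_term_determination = c("merge_as_synonym",
                                    "deprecate_with_replacement", "reject"),
  deprecation_dispute = c("uphold_deprecation", "revoke_deprecation"),
  extension_type = c("approve_term", "reject")
)

#' Create an empty issue queue
#' @return An object of class `issue_queue`.
#' @export
new_issue_queue <- function() {
  structure(list(issues = list(), next_id = 1L), class = "issue_queue")
}

issue_coalesce_key <- function(type, terms, proposed_text) {
  paste(type, paste(sort(terms %||% character(0)), collapse = ","),
        proposed_text %||% "", sep = "|")
}

#' Enqueue an ontology issue
#'
#' Duplicate `(type, payload)` pairs are coalesced: re-enqueueing returns
#' the existing issue id instead of creating a second issue.
#'
#' @param queue An `issue_queue`.
#' @param o A `carex_ontology`; payload term ids must exist.
#' @param type One of the issue types: `r paste(.issue_types, collapse = ", ")`.
#' @param terms Character vector of payload `TermId`s.
#' @param proposed_text Optional proposal text (definition, label,
#'   rationale).
#' @param contributor Optional user id.
#' @param form_flags Optional character vector of term-form lint flags.
#' @return List with `queue` (updated) and `id` of the (possibly
#'   pre-existing) issue.
#' @export
enqueue_issue <- function(queue, o, type, terms = character(0),
                          proposed_text = NULL, contributor = NULL,
                          form_flags = character(0)) {
  if (!type %in% .issue_types) {
    stop_charrec(sprintf("unknown issue type '%s'", type), class = "validation")
  }
  for (id in terms) get_term(o, id)
  key <- issue_coalesce_key(type, terms, proposed_text)
  for (iss in queue$issues) {
    if (iss$key == key && iss$status == "open") {
      return(list(queue = queue, id = iss$id))
    }
  }
  id <- sprintf("issue-%04d", queue$next_id)
  queue$issues[[id]] <- list(
    id = id, key = key, type = type, terms = terms,
    proposed_text = proposed_text, contributor = contributor,
    form_flags = form_flags, status = "open", resolution = NULL)
  queue$next_id <- queue$next_id + 1L
  list(queue = queue, id = id)
}

#' Construct a resolution record
#'
#' @param action One of: `r paste(.resolution_actions, collapse = ", ")`.
#' @param resolver Expert identifier.
#' @param term,superclass,survivor,duplicate,replacement,text
#'   Action-specific parameters; see Details.
#' @param time ISO-8601 timestamp (defaults to the system clock).
#'
#' @details Parameter schema by action: `assign_superclass(term,
#' superclass)`, `approve_definition(term, text)`, `approve_term(term[,
#' superclass])`, `merge_as_synonym(duplicate, survivor)` — the survivor
#' is always an explicit parameter, never inferred —
#' `deprecate_with_replacement(term, replacement)`,
#' `uphold_deprecation(term)`, `revoke_deprecation(term)`, `reject()`.
#' @return A `resolution` list.
#' @export
resolution <- function(action, resolver = "expert", term = NULL,
                       superclass = NULL, survivor = NULL, duplicate = NULL,
                       replacement = NULL, text = NULL, time = NULL) {
  if (!action %in% .resolution_actions) {
    stop_charrec(sprintf("unknown resolution action '%s'", action),
                 class = "validation")
  }
  structure(list(action = action, resolver = resolver, term = term,
                 superclass = superclass, survivor = survivor,
                 duplicate = duplicate, replacement = replacement,
                 text = text,
                 time = time %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC")),
            class = "resolution")
}

#' Resolve an open issue and apply the mutation to the ontology
#'
#' The resolution action must be compatible with the issue type. The
#' ontology mutation is applied atomically: it is validated before the
#' issue is closed, and on any failure an error is signalled and the
#' caller's ontology and queue are untouched (all objects are
#' copy-on-modify). `merge_as_synonym` moves the duplicate's label into
#' the survivor's exact synonyms and deprecates the duplicate with
#' `replaced_by` the survivor (set `merge_keep_synonym = FALSE` to rely
#' on the replacement chain only). `revoke_deprecation` brings the term
#' back to life and withdraws the corresponding matrix flags.
#'
#' @param queue An `issue_queue`.
#' @param id Open issue id.
#' @param res A [resolution()].
#' @param o A `carex_ontology`.
#' @param matrices Optional list of `cr_matrix` objects to notify.
#' @param merge_keep_synonym Keep merged labels matchable as exact
#'   synonyms of the survivor (default `TRUE`).
#' @return List with `queue`, `ontology`, `matrices` and `notices` (the
#'   ontology diff, see [emit_update_notices()]).
#' @export
resolve_issue <- function(queue, id, res, o, matrices = list(),
                          merge_keep_synonym = TRUE) {
  iss <- queue$issues[[id]]
  if (is.null(iss)) stop_charrec(sprintf("unknown issue '%s'", id), class = "not_found")
  if (iss$status != "open") {
    stop_charrec(sprintf("issue %s is already %s", id, iss$status), class = "state")
  }
  allowed <- .type_actions[[iss$type]]
  if (!res$action %in% allowed) {
    stop_charrec(sprintf("action '%s' is not valid for issue type '%s' (allowed: %s)",
                         res$action, iss$type, paste(allowed, collapse = ", ")),
                 class = "validation")
  }
  old <- o
  new <- switch(res$action,
    assign_superclass = {
      term <- res$term %||% iss$terms[[1L]]
      get_term(o, term); get_term(o, res$superclass)
      o$terms[[term]]$superclasses <- res$superclass
      o
    },
    approve_definition = {
      term <- res$term %||% iss$terms[[1L]]
      get_term(o, term)
      if (is.null(res$text) || !nzchar(trimws(res$text))) {
        stop_charrec("approve_definition requires non-empty definition text",
                     class = "validation")
      }
      o$terms[[term]]$definition <- res$text
      o
    },
    approve_term = {
      term <- res$term %||% iss$terms[[1L]]
      get_term(o, term)
      if (!is.null(res$superclass)) {
        get_term(o, res$superclass)
        o$terms[[term]]$superclasses <- res$superclass
      }
      o
    },
    merge_as_synonym = {
      dup <- res$duplicate %||% iss$terms[[1L]]
      surv <- res$survivor
      if (is.null(surv)) {
        stop_charrec("merge_as_synonym requires an explicit survivor",
                     class = "validation")
      }
      get_term(o, dup); get_term(o, surv)
      if (identical(dup, surv)) {
        stop_charrec("cannot merge a term into itself", class = "validation")
      }
      if (merge_keep_synonym) {
        o$terms[[surv]]$exact_synonyms <-
          union(o$terms[[surv]]$exact_synonyms, o$terms[[dup]]$label)
      }
      d <- deprecate_term(o, dup, surv)
      d$ontology
    },
    deprecate_with_replacement = {
      term <- res$term %||% iss$terms[[1L]]
      d <- deprecate_term(o, term, res$replacement)
      d$ontology
    },
    uphold_deprecation = o,
    revoke_deprecation = {
      term <- res$term %||% iss$terms[[1L]]
      get_term(o, term)
      o$terms[[term]]$deprecated <- FALSE
      o$terms[[term]]$replaced_by <- NULL
      o
    },
    reject = o
  )
  validate_ontology(new)
  if (res$action == "revoke_deprecation") {
    term <- res$term %||% iss$terms[[1L]]
    matrices <- lapply(matrices, withdraw_flags_for_term, term = term)
  }
  queue$issues[[id]]$status <- "resolved"
  queue$issues[[id]]$resolution <- unclass(res)
  un <- emit_update_notices(old, new, matrices)
  list(queue = queue, ontology = new, matrices = un$matrices,
       notices = un$notices)
}

#' Diff two ontology states into update notices
#'
#' Classifies the difference into the three notice categories surfaced
#' to matrix authors: `new_terms`, `deprecated_terms` and
#' `modified_terms` (definition, synonyms, superclass or replacement
#' changes on surviving terms). Deprecations additionally raise matrix
#' update flags via [scan_deprecated()].
#'
#' @param old,new `carex_ontology` states.
#' @param matrices Optional list of `cr_matrix` objects to re-scan.
#' @return List with `notices` (data frame: `category`, `term`, `label`)
#'   and `matrices` (re-scanned).
#' @export
emit_update_notices <- function(old, new, matrices = list()) {
  rows <- list()
  add <- function(category, id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, term = id, label = new$terms[[id]]$label,
      stringsAsFactors = FALSE)
  }
  for (id in setdiff(names(new$terms), names(old$terms))) add("new_terms", id)
  for (id in intersect(names(old$terms), names(new$terms))) {
    ot <- old$terms[[id]]; nt <- new$terms[[id]]
    if (!ot$deprecated && nt$deprecated) {
      add("deprecated_terms", id)
    } else if (!identical(ot[c("definition", "exact_synonyms", "broad_synonyms",
                               "not_recommended_synonyms", "superclasses",
                               "deprecated", "replaced_by")],
                          nt[c("definition", "exact_synonyms", "broad_synonyms",
                               "not_recommended_synonyms", "superclasses",
                               "deprecated", "replaced_by")])) {
      add("modified_terms", id)
    }
  }
  notices <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), term = character(0),
               label = character(0), stringsAsFactors = FALSE)
  matrices <- lapply(matrices, scan_deprecated, o = new)
  list(notices = notices, matrices = matrices)
}

#' List issues in a queue
#' @param queue An `issue_queue`.
#' @param status Optional filter (`"open"` or `"resolved"`).
#' @return Data frame of issues.
#' @export
list_issues <- function(queue, status = NULL) {
  issues <- queue$issues
  if (!is.null(status)) {
    issues <- Filter(function(i) i$status == status, issues)
  }
  if (!length(issues)) {
    return(data.frame(id = character(0), type = character(0),
                      terms = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(issues, function(i) data.frame(
    id = i$id, type = i$type, terms = paste(i$terms, collapse = ","),
    status = i$status, stringsAsFactors = FALSE)))
}

#' Persist a queue as an append-only JSON-lines log
#' @param queue An `issue_queue`.
#' @param path Output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
save_queue <- function(queue, path) {
  lines <- vapply(unname(queue$issues), function(i)
    jsonlite::toJSON(i, auto_unbox = TRUE, null = "null"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a queue from a JSON-lines log
#' @param path File written by [save_queue()].
#' @return An `issue_queue`.
#' @export
load_queue <- function(path) {
  q <- new_issue_queue()
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    i <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    i$terms <- unlist(i$terms) %||% character(0)
    i$form_flags <- unlist(i$form_flags) %||% character(0)
    q$issues[[i$id]] <- i
    num <- suppressWarnings(as.integer(sub("^issue-", "", i$id)))
    if (!is.na(num) && num >= q$next_id) q$next_id <- num + 1L
  }
  q
}
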