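# In-memory ontology model: term store, Turtle load/save, term lifecycle
# (minting, deprecation, replacement chains), hierarchy queries and
# structural validation.
#
# Terms are plain lists held in a named list keyed by CURIE; all mutating
# operations are functional (they return the updated ontology). Identifiers
# are `carex:` CURIEs with a zero-padded 7-digit local part, minted
# monotonically and never reused — deprecation preserves the ID so that
# recorded matrices stay resolvable.

.root_labels <- c("anatomical_entity", "quality", "unit", "scope",
                  "to_review", "collection")

.assertion_predicates <- c("measured_from", "measured_to", "measured_include",
                           "measured_exclude", "measured_at", "in_collection",
                           "maybe_part_of", "join_with")

empty_assertions <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), stringsAsFactors = FALSE)
}

#' Create an empty ontology with the six root branches
#'
#' The six top-level classes (`anatomical_entity`, `quality`, `unit`,
#' `scope`, `to_review`, `collection`) are minted first, in fixed order,
#' so their identifiers are stable across regenerations.
#'
#' @param prefix CURIE prefix used for minted term identifiers.
#' @return An object of class `carex_ontology`.
#' @export
new_ontology <- function(prefix = "carex") {
  o <- structure(list(
    prefix = prefix,
    terms = list(),
    assertions = empty_assertions(),
    roots = character(0),
    next_id = 1L,
    minted = data.frame(id = character(0), label = character(0),
                        stringsAsFactors = FALSE),
    extras = NULL
  ), class = "carex_ontology")
  for (lab in .root_labels) {
    o <- mint_term(o, lab, definition = NULL, superclasses = character(0))$ontology
  }
  o$roots <- vapply(.root_labels, function(lab) term_by_label(o, lab)$id,
                    character(1))
  o
}

new_term_record <- function(id, label, definition = NULL) {
  list(id = id, label = label, definition = definition,
       exact_synonyms = character(0), broad_synonyms = character(0),
       not_recommended_synonyms = character(0),
       superclasses = character(0), deprecated = FALSE,
       replaced_by = NULL, elucidation = NULL,
       cross_refs = character(0), in_collections = character(0),
       contributor = NULL)
}

format_term_id <- function(prefix, n) sprintf("%s:%07d", prefix, n)

term_by_label <- function(o, label) {
  for (t in o$terms) if (t$label == label) return(t)
  NULL
}

term_exists <- function(o, id) !is.null(o$terms[[id]])

get_term <- function(o, id) {
  t <- o$terms[[id]]
  if (is.null(t)) {
    stop_charrec(sprintf("unknown term '%s'", id), class = "not_found",
                 data = list(term = id))
  }
  t
}

# Internal mint: no duplicate checks, no issue queueing.
mint_term <- function(o, label, definition = NULL, superclasses = character(0),
                      contributor = NULL) {
  id <- format_term_id(o$prefix, o$next_id)
  t <- new_term_record(id, label, definition)
  t$superclasses <- superclasses
  t$contributor <- contributor
  o$terms[[id]] <- t
  o$next_id <- o$next_id + 1L
  o$minted <- rbind(o$minted,
                    data.frame(id = id, label = label, stringsAsFactors = FALSE))
  list(ontology = o, term = t)
}

#' Add a user-contributed term
#'
#' Mints the next persistent identifier and files the term under the given
#' superclass, or under the `to_review` branch when none is given (the
#' normal route for end-user contributions awaiting expert review). The
#' term is immediately usable in matrices.
#'
#' @param o A `carex_ontology`.
#' @param label Term label; normalized with [normalize_label()].
#' @param definition Optional definition text.
#' @param contributor Optional user identifier recorded on the term.
#' @param superclass Optional parent `TermId`; defaults to `to_review`.
#' @return A list with elements `ontology` (updated), `term` (the new
#'   term record) and `warnings` (term-form flags, see
#'   [validate_term_form()]).
#' @export
add_term <- function(o, label, definition = NULL, contributor = NULL,
                     superclass = NULL) {
  label <- normalize_label(label)
  if (!nzchar(label)) {
    stop_charrec("term label is empty after normalization", class = "validation")
  }
  for (t in o$terms) {
    if (!t$deprecated &&
        (t$label == label || label %in% vapply(t$exact_synonyms, normalize_label, character(1)))) {
      stop_charrec(sprintf("label '%s' duplicates existing term %s (%s)",
                           label, t$id, t$label),
                   class = "duplicate", data = list(existing = t$id))
    }
  }
  if (is.null(superclass)) {
    superclass <- unname(o$roots[["to_review"]])
  } else if (!term_exists(o, superclass)) {
    stop_charrec(sprintf("superclass '%s' does not exist", superclass),
                 class = "not_found", data = list(term = superclass))
  }
  res <- mint_term(o, label, definition, superclasses = superclass,
                   contributor = contributor)
  report <- validate_term_form(label)
  list(ontology = res$ontology, term = res$term, warnings = report$flags)
}

#' Deprecate a term in favour of a replacement
#'
#' The term keeps its identifier; `replaced_by` guides users (and the
#' matrix update machinery) to the preferred term. Matrices passed in
#' `matrices` are scanned and one update notice is emitted per recorded
#' state that references the deprecated term.
#'
#' @param o A `carex_ontology`.
#' @param id `TermId` to deprecate.
#' @param replacement `TermId` of the preferred term.
#' @param matrices Optional list of `cr_matrix` objects to scan.
#' @return A list with `ontology` (updated) and `notices` (data frame of
#'   affected matrix states: matrix index, taxon, sample, character).
#' @export
deprecate_term <- function(o, id, replacement, matrices = list()) {
  t <- get_term(o, id)
  if (!term_exists(o, replacement)) {
    stop_charrec(sprintf("replacement '%s' does not exist", replacement),
                 class = "not_found", data = list(term = replacement))
  }
  if (identical(id, replacement)) {
    stop_charrec("a term cannot replace itself", class = "cycle")
  }
  # walking the existing replacement chain from the proposed replacement
  # must never come back to `id`
  seen <- character(0)
  cur <- replacement
  while (!is.null(cur)) {
    if (cur == id) {
      stop_charrec(sprintf("deprecating %s -> %s would create a replacement cycle",
                           id, replacement), class = "cycle")
    }
    if (cur %in% seen) break
    seen <- c(seen, cur)
    cur <- o$terms[[cur]]$replaced_by
  }
  o$terms[[id]]$deprecated <- TRUE
  o$terms[[id]]$replaced_by <- replacement
  notices <- scan_term_usage(matrices, id)
  list(ontology = o, notices = notices)
}

scan_term_usage <- function(matrices, id) {
  rows <- list()
  for (mi in seq_along(matrices)) {
    m <- matrices[[mi]]
    for (key in names(m$cells)) {
      cell <- m$cells[[key]]
      for (si in seq_along(cell$states)) {
        st <- cell$states[[si]]
        if (identical(st$kind, "term") && identical(st$term, id)) {
          rows[[length(rows) + 1L]] <- data.frame(
            matrix = mi, taxon = cell$taxon, sample = cell$sample,
            character = cell$character, state = si, term = id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(matrix = integer(0), taxon = character(0), sample = character(0),
               character = character(0), state = integer(0), term = character(0),
               stringsAsFactors = FALSE)
}

#' Resolve a replacement chain to its live endpoint
#'
#' Follows `replaced_by` links transitively and returns the first
#' non-deprecated term; a non-deprecated input is returned unchanged.
#'
#' @param o A `carex_ontology`.
#' @param id Starting `TermId`.
#' @return The `TermId` of the live replacement.
#' @export
resolve_replacement_chain <- function(o, id) {
  t <- get_term(o, id)
  seen <- character(0)
  cur <- id
  repeat {
    term <- get_term(o, cur)
    if (!term$deprecated) return(cur)
    if (is.null(term$replaced_by)) {
      stop_charrec(sprintf("deprecated term %s has no replacement", cur),
                   class = "unresolved_deprecation", data = list(term = cur))
    }
    if (cur %in% seen) {
      stop_charrec(sprintf("replacement chain starting at %s is cyclic", id),
                   class = "cycle", data = list(term = id))
    }
    seen <- c(seen, cur)
    cur <- term$replaced_by
  }
}

children_of <- function(o, id) {
  kids <- Filter(function(t) id %in% t$superclasses, o$terms)
  labs <- vapply(kids, function(t) t$label, character(1))
  ids <- vapply(kids, function(t) t$id, character(1))
  ids[order(labs, ids)]
}

#' List the live descendants of a term
#'
#' Depth-first traversal with children visited in label order; deprecated
#' terms (and their otherwise-unreachable descendants) are excluded. This
#' is the ordering used when a branch of the ontology is offered for value
#' selection.
#'
#' @param o A `carex_ontology`.
#' @param id Root `TermId` of the branch.
#' @return Character vector of descendant `TermId`s (excluding `id`).
#' @export
branch_of <- function(o, id) {
  get_term(o, id)
  out <- character(0)
  walk <- function(node) {
    for (kid in children_of(o, node)) {
      if (o$terms[[kid]]$deprecated) next
      if (kid %in% out) next
      out <<- c(out, kid)
      walk(kid)
    }
  }
  walk(id)
  out
}

root_ancestors <- function(o, id) {
  roots <- character(0)
  seen <- character(0)
  walk <- function(node) {
    if (node %in% seen) return(invisible(NULL))
    seen <<- c(seen, node)
    t <- o$terms[[node]]
    if (!length(t$superclasses)) {
      roots <<- union(roots, node)
    } else {
      for (s in t$superclasses) if (!is.null(o$terms[[s]])) walk(s)
    }
  }
  walk(id)
  roots
}

subclass_has_cycle <- function(o) {
  state <- new.env(parent = emptyenv())
  cyc <- NULL
  visit <- function(id) {
    st <- state[[id]] %||% 0L
    if (st == 1L) { cyc <<- id; return(TRUE) }
    if (st == 2L) return(FALSE)
    state[[id]] <- 1L
    t <- o$terms[[id]]
    for (s in t$superclasses) {
      if (!is.null(o$terms[[s]]) && visit(s)) return(TRUE)
    }
    state[[id]] <- 2L
    FALSE
  }
  for (id in names(o$terms)) if (visit(id)) return(cyc)
  NULL
}

#' Validate the structural invariants of an ontology
#'
#' Checks that every superclass reference resolves, the subclass graph and
#' the replacement graph are acyclic, non-deprecated terms carry no
#' `replaced_by` link, synonym strings appear in at most one tier per
#' term, and every term is reachable from exactly one root branch (terms
#' filed under `to_review` are exempt from the single-branch rule).
#'
#' @param o A `carex_ontology`.
#' @return `o`, invisibly, if valid; otherwise a validation error listing
#'   the offending identifiers.
#' @export
validate_ontology <- function(o) {
  problems <- character(0)
  for (t in o$terms) {
    dangling <- t$superclasses[!vapply(t$superclasses, term_exists, logical(1), o = o)]
    if (length(dangling)) {
      problems <- c(problems, sprintf("%s: undeclared superclass %s",
                                      t$id, paste(dangling, collapse = ", ")))
    }
    if (!t$deprecated && !is.null(t$replaced_by)) {
      problems <- c(problems, sprintf("%s: replaced_by on a live term", t$id))
    }
    tiers <- list(label = t$label, exact = t$exact_synonyms,
                  broad = t$broad_synonyms, not_recommended = t$not_recommended_synonyms)
    all_strings <- unlist(tiers, use.names = FALSE)
    if (anyDuplicated(all_strings)) {
      dup <- unique(all_strings[duplicated(all_strings)])
      problems <- c(problems, sprintf("%s: string in multiple synonym tiers: %s",
                                      t$id, paste(dup, collapse = ", ")))
    }
  }
  cyc <- subclass_has_cycle(o)
  if (!is.null(cyc)) {
    problems <- c(problems, sprintf("subclass graph contains a cycle through %s", cyc))
  }
  # replacement graph acyclicity
  for (t in o$terms) {
    if (t$deprecated && !is.null(t$replaced_by)) {
      seen <- t$id
      cur <- t$replaced_by
      while (!is.null(cur)) {
        if (cur %in% seen) {
          problems <- c(problems, sprintf("replacement cycle through %s", t$id))
          break
        }
        seen <- c(seen, cur)
        cur <- if (!is.null(o$terms[[cur]])) o$terms[[cur]]$replaced_by else NULL
      }
    }
  }
  if (is.null(cyc)) {
    to_review <- unname(o$roots["to_review"])
    for (t in o$terms) {
      if (t$id %in% o$roots) next
      ra <- root_ancestors(o, t$id)
      if (length(ra) == 0L || (length(ra) > 1L && !(to_review %in% ra))) {
        problems <- c(problems,
                      sprintf("%s: reachable from %d root branches", t$id, length(ra)))
      }
    }
  }
  # assertions reference existing terms and closed predicate set
  a <- o$assertions
  bad_pred <- setdiff(unique(a$predicate), .assertion_predicates)
  if (length(bad_pred)) {
    problems <- c(problems, sprintf("unknown assertion predicate: %s",
                                    paste(bad_pred, collapse = ", ")))
  }
  for (col in c("subject", "object")) {
    missing <- a[[col]][!vapply(a[[col]], term_exists, logical(1), o = o)]
    if (length(missing)) {
      problems <- c(problems, sprintf("assertion %s refers to unknown term(s): %s",
                                      col, paste(unique(missing), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop_charrec(paste0("ontology validation failed:\n  ",
                        paste(problems, collapse = "\n  ")),
                 class = "validation", data = list(problems = problems))
  }
  invisible(o)
}

#' Assert a property between two terms
#'
#' @param o A `carex_ontology`.
#' @param subject,object Existing `TermId`s.
#' @param predicate One of the closed predicate set: `measured_from`,
#'   `measured_to`, `measured_include`, `measured_exclude`, `measured_at`,
#'   `in_collection`, `maybe_part_of`, `join_with`.
#' @return The updated ontology.
#' @export
assert_property <- function(o, subject, predicate, object) {
  if (!predicate %in% .assertion_predicates) {
    stop_charrec(sprintf("unknown predicate '%s'", predicate), class = "validation")
  }
  get_term(o, subject); get_term(o, object)
  row <- data.frame(subject = subject, predicate = predicate, object = object,
                    stringsAsFactors = FALSE)
  if (!nrow(merge(o$assertions, row))) {
    o$assertions <- rbind(o$assertions, row)
  }
  if (predicate == "in_collection") {
    o$terms[[subject]]$in_collections <-
      union(o$terms[[subject]]$in_collections, object)
  }
  o
}

# ---- Turtle serialization ---------------------------------------------------

.term_predicates <- c(
  label = "rdfs:label",
  definition = "obo:IAO_0000115",
  exact = "obo:hasExactSynonym",
  broad = "obo:hasBroadSynonym",
  not_recommended = "carex:has_not_recommended_synonym",
  deprecated = "owl:deprecated",
  replaced_by = "carex:term_replaced_by",
  elucidation = "oai:elucidation",
  xref = "obo:hasDbXref",
  subclass = "rdfs:subClassOf"
)

ontology_triples <- function(o) {
  rows <- list()
  add <- function(s, p, obj, lit = FALSE, dtype = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      graph = NA_character_, s = s, p = p, o = obj, lit = lit, dtype = dtype,
      stringsAsFactors = FALSE)
  }
  ids <- names(o$terms)
  labs <- vapply(o$terms, function(t) t$label, character(1))
  ord <- ids[order(labs, ids)]
  # roots first (fixed branch order), then remaining terms by label
  ord <- c(unname(o$roots), setdiff(ord, unname(o$roots)))
  for (id in ord) {
    t <- o$terms[[id]]
    add(id, "rdf:type", "owl:Class")
    add(id, "rdfs:label", t$label, lit = TRUE)
    for (s in sort(t$superclasses)) add(id, "rdfs:subClassOf", s)
    if (!is.null(t$definition)) add(id, .term_predicates[["definition"]], t$definition, lit = TRUE)
    for (s in sort(t$exact_synonyms)) add(id, .term_predicates[["exact"]], s, lit = TRUE)
    for (s in sort(t$broad_synonyms)) add(id, .term_predicates[["broad"]], s, lit = TRUE)
    for (s in sort(t$not_recommended_synonyms)) add(id, .term_predicates[["not_recommended"]], s, lit = TRUE)
    if (t$deprecated) {
      add(id, "owl:deprecated", "true", lit = TRUE, dtype = "xsd:boolean")
      if (!is.null(t$replaced_by)) add(id, "carex:term_replaced_by", t$replaced_by)
    }
    if (!is.null(t$elucidation)) add(id, "oai:elucidation", paste0("<", t$elucidation, ">"))
    for (x in sort(t$cross_refs)) add(id, .term_predicates[["xref"]], x, lit = TRUE)
    if (!is.null(t$contributor)) add(id, "carex:contributed_by", t$contributor, lit = TRUE)
  }
  a <- o$assertions
  if (nrow(a)) {
    a <- a[order(a$subject, a$predicate, a$object), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      add(a$subject[[i]], paste0("carex:", a$predicate[[i]]), a$object[[i]])
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(o$extras) && nrow(o$extras)) df <- rbind(df, o$extras)
  df
}

#' Save an ontology as Turtle
#'
#' Emission order is deterministic (roots in branch order, then terms
#' sorted by label, fixed predicate order) so repeated saves of the same
#' ontology are byte-identical. Unknown triples preserved from a previous
#' load are re-emitted verbatim.
#'
#' @param o A `carex_ontology`.
#' @param path Output file path (`.ttl`).
#' @return `path`, invisibly.
#' @export
save_ontology <- function(o, path) {
  write_turtle(ontology_triples(o), path)
  invisible(path)
}

#' Load an ontology from Turtle
#'
#' Accepts documents following this package's schema: terms are
#' `owl:Class` subjects with an `rdfs:label`; synonym tiers, deprecation
#' markers, replacement links, cross-references and measurement-landmark
#' assertions are read from their dedicated predicates. Triples with
#' predicates outside the schema are preserved in an opaque extras store
#' and re-emitted on save. The loaded ontology is validated before it is
#' returned.
#'
#' @param path Path to a Turtle file.
#' @return A `carex_ontology`.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) {
    stop_charrec(sprintf("file '%s' does not exist", path), class = "io")
  }
  df <- parse_rdf(path = path)
  known <- c(unname(.term_predicates), "rdf:type", "carex:contributed_by",
             paste0("carex:", .assertion_predicates))
  classes <- unique(df$s[df$p == "rdf:type" & df$o == "owl:Class"])
  o <- structure(list(
    prefix = "carex", terms = list(), assertions = empty_assertions(),
    roots = character(0), next_id = 1L,
    minted = data.frame(id = character(0), label = character(0),
                        stringsAsFactors = FALSE),
    extras = NULL
  ), class = "carex_ontology")
  extras <- df[!(df$s %in% classes) | !(df$p %in% known), , drop = FALSE]
  for (id in classes) {
    sel <- df[df$s == id, , drop = FALSE]
    lab <- sel$o[sel$p == "rdfs:label"]
    if (!length(lab)) {
      stop_charrec(sprintf("%s: class %s has no rdfs:label", path, id),
                   class = "validation", data = list(term = id))
    }
    t <- new_term_record(id, lab[[1L]])
    t$superclasses <- sel$o[sel$p == "rdfs:subClassOf"]
    defn <- sel$o[sel$p == .term_predicates[["definition"]]]
    if (length(defn)) t$definition <- defn[[1L]]
    t$exact_synonyms <- sel$o[sel$p == .term_predicates[["exact"]]]
    t$broad_synonyms <- sel$o[sel$p == .term_predicates[["broad"]]]
    t$not_recommended_synonyms <- sel$o[sel$p == .term_predicates[["not_recommended"]]]
    t$deprecated <- any(sel$p == "owl:deprecated" & sel$o == "true")
    rb <- sel$o[sel$p == "carex:term_replaced_by"]
    if (length(rb)) t$replaced_by <- rb[[1L]]
    el <- sel$o[sel$p == "oai:elucidation"]
    if (length(el)) t$elucidation <- gsub("^<|>$", "", el[[1L]])
    t$cross_refs <- sel$o[sel$p == .term_predicates[["xref"]]]
    ctb <- sel$o[sel$p == "carex:contributed_by"]
    if (length(ctb)) t$contributor <- ctb[[1L]]
    o$terms[[id]] <- t
  }
  arows <- df[df$p %in% paste0("carex:", .assertion_predicates) &
                df$s %in% classes, , drop = FALSE]
  if (nrow(arows)) {
    o$assertions <- data.frame(subject = arows$s,
                               predicate = sub("^carex:", "", arows$p),
                               object = arows$o, stringsAsFactors = FALSE)
    for (i in which(o$assertions$predicate == "in_collection")) {
      s <- o$assertions$subject[[i]]
      o$terms[[s]]$in_collections <-
        union(o$terms[[s]]$in_collections, o$assertions$object[[i]])
    }
  }
  if (nrow(extras)) o$extras <- extras
  # roots: terms with no superclass
  root_ids <- names(o$terms)[!vapply(o$terms, function(t) length(t$superclasses) > 0, logical(1))]
  root_labs <- vapply(root_ids, function(id) o$terms[[id]]$label, character(1))
  o$roots <- stats::setNames(root_ids, root_labs)[
    intersect(.root_labels, root_labs)]
  unknown_roots <- setdiff(root_labs, .root_labels)
  if (length(unknown_roots)) {
    stop_charrec(sprintf("%s: unrecognized top-level class(es): %s", path,
                         paste(unknown_roots, collapse = ", ")),
                 class = "validation", data = list(problems = unknown_roots))
  }
  # resume minting after the highest local id seen for our prefix
  local <- suppressWarnings(as.integer(sub("^[^:]+:", "",
           grep(paste0("^", o$prefix, ":[0-9]+$"), names(o$terms), value = TRUE))))
  o$next_id <- if (length(local) && any(!is.na(local))) max(local, na.rm = TRUE) + 1L else 1L
  o$minted <- data.frame(id = names(o$terms),
                         label = vapply(o$terms, function(t) t$label, character(1)),
                         stringsAsFactors = FALSE)
  validate_ontology(o)
  o
}

#' @export
print.carex_ontology <- function(x, ...) {
  n_dep <- sum(vapply(x$terms, function(t) t$deprecated, logical(1)))
  cat(sprintf("<carex_ontology> %d terms (%d deprecated), %d assertions, %d roots\n",
              length(x$terms), n_dep, nrow(x$assertions), length(x$roots)))
  invisible(x)
}
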