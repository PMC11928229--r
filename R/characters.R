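# Character model: categorical and numerical characters with measurement
# landmarks, units, scopes and constraint clauses, plus the decision-tree
# character recommender. Characters get their own `chr:` CURIE namespace,
# distinct from ontology term IDs: they are ontology-linked records, not
# ontology classes.

#' Create an empty character registry
#' @return An object of class `chr_registry`.
#' @export
new_registry <- function() {
  structure(list(characters = list(), next_id = 1L), class = "chr_registry")
}

#' A constraint clause attached to a character
#'
#' Three kinds mirror the constraint grammar for complex characters:
#' structural (`+S`, associated with some organ), positional (`+P`, the
#' location of a measurement, e.g. at mid-height) and distance (`+D`,
#' relative to a reference organ). Percent-type magnitudes are stored as
#' ratios in `[0, 1]` so they are arithmetic-ready; display formatting is
#' derived.
#'
#' @param kind One of `"structural"`, `"positional"`, `"distance"`.
#' @param text Display text of the clause.
#' @param anchor Optional anchor `TermId` (required for distance clauses).
#' @param magnitude Optional numeric magnitude (required for distance
#'   clauses); percentages as ratio 0-1.
#' @param unit Optional unit: `"ratio"` or a unit `TermId`.
#' @param direction Optional direction token (e.g. `"below"`, `"above"`).
#' @return A `constraint_clause` list.
#' @export
constraint_clause <- function(kind = c("structural", "positional", "distance"),
                              text, anchor = NULL, magnitude = NULL,
                              unit = NULL, direction = NULL) {
  kind <- match.arg(kind)
  if (kind == "distance" && (is.null(anchor) || is.null(magnitude))) {
    stop_charrec("distance constraints require an anchor and a magnitude",
                 class = "validation")
  }
  structure(list(kind = kind, text = text, anchor = anchor,
                 magnitude = magnitude, unit = unit, direction = direction),
            class = "constraint_clause")
}

#' A landmark specification for a numerical character
#'
#' Reference points that disambiguate what a measurement spans. At least
#' one of `from`, `to`, `at` must be given; `include`/`exclude` refine
#' which parts count. Slots are verified against the ontology when the
#' character is defined.
#'
#' @param from,to,at Optional `TermId`s.
#' @param include,exclude Character vectors of `TermId`s.
#' @return A `landmark_spec` list.
#' @export
landmark_spec <- function(from = NULL, to = NULL, at = NULL,
                          include = character(0), exclude = character(0)) {
  if (is.null(from) && is.null(to) && is.null(at)) {
    stop_charrec("a landmark needs at least one of from/to/at",
                 class = "validation")
  }
  structure(list(from = from, to = to, at = at, include = include,
                 exclude = exclude, verified = list()),
            class = "landmark_spec")
}

# A slot is verified iff its term exists in the ontology and is live.
verify_landmark <- function(o, lm) {
  check <- function(id) !is.null(id) && term_exists(o, id) && !get_term(o, id)$deprecated
  lm$verified <- list(
    from = if (!is.null(lm$from)) check(lm$from),
    to = if (!is.null(lm$to)) check(lm$to),
    at = if (!is.null(lm$at)) check(lm$at),
    include = vapply(lm$include, check, logical(1)),
    exclude = vapply(lm$exclude, check, logical(1))
  )
  lm
}

landmark_warnings <- function(lm) {
  bad <- character(0)
  for (slot in c("from", "to", "at")) {
    v <- lm$verified[[slot]]
    if (!is.null(v) && !v) bad <- c(bad, sprintf("%s=%s", slot, lm[[slot]]))
  }
  for (slot in c("include", "exclude")) {
    v <- lm$verified[[slot]]
    if (length(v)) bad <- c(bad, sprintf("%s=%s", slot, lm[[slot]][!v]))
  }
  if (length(bad)) sprintf("unverified landmark slot(s): %s",
                           paste(bad, collapse = ", "))
  else character(0)
}

check_branch <- function(o, id, root_label, what) {
  root <- unname(o$roots[[root_label]])
  anc <- root_ancestors(o, id)
  if (!(root %in% anc)) {
    stop_charrec(sprintf("%s term %s is not in the %s branch",
                         what, id, root_label),
                 class = "validation", data = list(term = id))
  }
  invisible(TRUE)
}

register_character <- function(reg, char) {
  id <- sprintf("chr:%07d", reg$next_id)
  char$id <- id
  reg$characters[[id]] <- char
  reg$next_id <- reg$next_id + 1L
  list(registry = reg, character = char)
}

#' Define a numerical measurement character
#'
#' Numerical characters must state a measurement landmark and a unit
#' drawn from the ontology's unit class, so recorded values are
#' comparable across treatments. Landmark slots are verified against the
#' ontology; unverified slots are reported as warnings (new landmark
#' terms can be proposed through the resolution workflow first).
#'
#' @param o A `carex_ontology`.
#' @param registry A `chr_registry`.
#' @param entity `TermId` of the structure described (anatomical entity
#'   branch).
#' @param quality `TermId` of the measured quality (quality branch).
#' @param landmark A [landmark_spec()].
#' @param unit `TermId` from the unit branch.
#' @param scope Optional `TermId` from the scope branch.
#' @param constraints List of [constraint_clause()]s.
#' @param organ_tab Grouping key for matrix tabs and descriptions.
#' @param recommended Is the character part of the recommended core set?
#' @return List with `registry`, `character` and `warnings`.
#' @export
define_numerical_character <- function(o, registry, entity, quality, landmark,
                                       unit, scope = NULL,
                                       constraints = list(),
                                       organ_tab = "general",
                                       recommended = FALSE) {
  if (missing(landmark) || is.null(landmark)) {
    stop_charrec("a numerical character requires a landmark", class = "validation")
  }
  if (missing(unit) || is.null(unit)) {
    stop_charrec("a numerical character requires a unit", class = "validation")
  }
  get_term(o, entity); get_term(o, quality); get_term(o, unit)
  check_branch(o, entity, "anatomical_entity", "entity")
  check_branch(o, quality, "quality", "quality")
  check_branch(o, unit, "unit", "unit")
  if (!is.null(scope)) check_branch(o, scope, "scope", "scope")
  lm <- verify_landmark(o, landmark)
  char <- structure(list(
    id = NULL, kind = "numerical", entity = entity, quality = quality,
    organ_tab = organ_tab, constraints = constraints, landmark = lm,
    unit = unit, scope = scope, recommended = recommended
  ), class = "cr_character")
  res <- register_character(registry, char)
  list(registry = res$registry, character = res$character,
       warnings = landmark_warnings(lm))
}

#' Define a categorical (quality-of-entity) character
#'
#' @inheritParams define_numerical_character
#' @return List with `registry`, `character` and `warnings`.
#' @export
define_categorical_character <- function(o, registry, entity, quality,
                                         constraints = list(),
                                         organ_tab = "general",
                                         recommended = FALSE) {
  get_term(o, entity); get_term(o, quality)
  check_branch(o, entity, "anatomical_entity", "entity")
  # a quality may still sit under to_review (user-contributed, awaiting
  # categorization): allowed, but flagged for the curation queue
  warnings <- character(0)
  anc <- root_ancestors(o, quality)
  if (unname(o$roots[["to_review"]]) %in% anc) {
    warnings <- c(warnings, sprintf(
      "quality term %s is under review; a re-categorization issue should be filed",
      quality))
  } else {
    check_branch(o, quality, "quality", "quality")
  }
  char <- structure(list(
    id = NULL, kind = "categorical", entity = entity, quality = quality,
    organ_tab = organ_tab, constraints = constraints, landmark = NULL,
    unit = NULL, scope = NULL, recommended = isTRUE(recommended)
  ), class = "cr_character")
  res <- register_character(registry, char)
  list(registry = res$registry, character = res$character, warnings = warnings)
}

#' Display name of a character
#' @param o A `carex_ontology`.
#' @param char A `cr_character`.
#' @return e.g. `"growth form of plant"`.
#' @export
character_name <- function(o, char) {
  base <- sprintf("%s of %s",
                  display_label(get_term(o, char$quality)$label),
                  display_label(get_term(o, char$entity)$label))
  if (length(char$constraints)) {
    base <- paste(base,
                  paste(vapply(char$constraints, function(cc) cc$text, character(1)),
                        collapse = " "))
  }
  base
}

# ---- decision tree ----------------------------------------------------------

#' Load a decision tree for character recommendation
#'
#' The tree is a rooted DAG of questions; each answer names the next node
#' (or `null` for a terminal) and the set of character ids it activates.
#' Schema: `{"root": id, "nodes": {id: {"question": text, "options":
#' {answer: {"next": id|null, "activates": [chr ids]}}}}}`.
#'
#' @param path Path to the JSON tree file.
#' @param registry Optional registry; referenced character ids are checked.
#' @return A `decision_tree` list.
#' @export
load_decision_tree <- function(path, registry = NULL) {
  tree <- jsonlite::read_json(path)
  validate_decision_tree(tree, registry)
  structure(tree, class = "decision_tree")
}

validate_decision_tree <- function(tree, registry = NULL) {
  if (is.null(tree$root) || is.null(tree$nodes[[tree$root]])) {
    stop_charrec("decision tree has no root node", class = "validation")
  }
  # acyclicity by DFS
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- state[[id]] %||% 0L
    if (st == 1L) stop_charrec(sprintf("decision tree cycle through node '%s'", id),
                               class = "cycle")
    if (st == 2L) return(invisible(NULL))
    state[[id]] <- 1L
    node <- tree$nodes[[id]]
    for (opt in node$options) {
      if (!is.null(opt[["next"]])) {
        if (is.null(tree$nodes[[opt[["next"]]]])) {
          stop_charrec(sprintf("decision tree references unknown node '%s'",
                               opt[["next"]]), class = "validation")
        }
        visit(opt[["next"]])
      }
      if (!is.null(registry)) {
        for (cid in unlist(opt$activates)) {
          if (is.null(registry$characters[[cid]])) {
            stop_charrec(sprintf("decision tree activates unknown character '%s'", cid),
                         class = "validation")
          }
        }
      }
    }
    state[[id]] <- 2L
  }
  visit(tree$root)
  invisible(tree)
}

#' Recommend characters from the standard set and a decision tree
#'
#' Starts from the recommended core set (every treatment of the group
#' should record these, keeping descriptions parallel) and adds the
#' characters activated along the answered path through the decision
#' tree. Branches pruned by an answer contribute nothing: e.g. if the
#' inflorescence is unbranched, inflorescence-unit characters never
#' appear. Overlaps are de-duplicated keeping first occurrence.
#'
#' @param registry A `chr_registry`.
#' @param tree A `decision_tree` (optional; `NULL` for core set only).
#' @param answers Named list mapping node id to the chosen answer.
#' @param o Optional ontology used to verify activated characters'
#'   terms are live.
#' @return Ordered character vector of character ids.
#' @export
recommended_characters <- function(registry, tree = NULL, answers = list(),
                                   o = NULL) {
  core <- names(registry$characters)[vapply(registry$characters,
                                            function(ch) isTRUE(ch$recommended),
                                            logical(1))]
  out <- core
  if (!is.null(tree)) {
    visited <- character(0)
    cur <- tree$root
    while (!is.null(cur)) {
      visited <- c(visited, cur)
      ans <- answers[[cur]]
      if (is.null(ans)) break
      node <- tree$nodes[[cur]]
      opt <- node$options[[ans]]
      if (is.null(opt)) {
        stop_charrec(sprintf("node '%s' has no option '%s'", cur, ans),
                     class = "validation")
      }
      out <- c(out, unlist(opt$activates))
      cur <- opt[["next"]]
    }
    stray <- setdiff(names(answers), visited)
    if (length(stray)) {
      stop_charrec(sprintf("answer(s) for unreachable node(s): %s",
                           paste(stray, collapse = ", ")),
                   class = "inconsistency")
    }
  }
  out <- out[!duplicated(out)]
  for (cid in out) {
    ch <- registry$characters[[cid]]
    if (is.null(ch)) {
      stop_charrec(sprintf("recommended character '%s' is not in the registry", cid),
                   class = "not_found")
    }
    if (!is.null(o)) {
      for (tid in c(ch$entity, ch$quality)) {
        if (get_term(o, tid)$deprecated) {
          stop_charrec(sprintf("character %s references deprecated term %s",
                               cid, tid), class = "validation")
        }
      }
    }
  }
  out
}

# ---- JSON import/export -----------------------------------------------------

character_to_list <- function(ch) {
  list(id = ch$id, kind = ch$kind, entity = ch$entity, quality = ch$quality,
       organ_tab = ch$organ_tab,
       constraints = lapply(ch$constraints, unclass),
       landmark = if (!is.null(ch$landmark))
         list(from = ch$landmark$from, to = ch$landmark$to, at = ch$landmark$at,
              include = as.list(ch$landmark$include),
              exclude = as.list(ch$landmark$exclude)),
       unit = ch$unit, scope = ch$scope, recommended = ch$recommended)
}

#' Export a character registry to JSON
#' @param registry A `chr_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_characters <- function(registry, path) {
  jsonlite::write_json(lapply(unname(registry$characters), character_to_list),
                       path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Import a character registry from JSON
#' @param path JSON file written by [export_characters()] (or authored by
#'   hand to the same schema).
#' @param o Optional ontology; term references are checked when given.
#' @return A `chr_registry`.
#' @export
import_characters <- function(path, o = NULL) {
  data <- jsonlite::read_json(path)
  reg <- new_registry()
  for (cl in data) {
    lm <- NULL
    if (!is.null(cl$landmark)) {
      lm <- landmark_spec(from = cl$landmark$from, to = cl$landmark$to,
                          at = cl$landmark$at,
                          include = unlist(cl$landmark$include) %||% character(0),
                          exclude = unlist(cl$landmark$exclude) %||% character(0))
      if (!is.null(o)) lm <- verify_landmark(o, lm)
    }
    ch <- structure(list(
      id = cl$id, kind = cl$kind, entity = cl$entity, quality = cl$quality,
      organ_tab = cl$organ_tab %||% "general",
      constraints = lapply(cl$constraints, function(cc)
        constraint_clause(cc$kind, cc$text, cc$anchor, cc$magnitude,
                          cc$unit, cc$direction)),
      landmark = lm, unit = cl$unit, scope = cl$scope,
      recommended = isTRUE(cl$recommended)
    ), class = "cr_character")
    if (!is.null(o)) {
      get_term(o, ch$entity); get_term(o, ch$quality)
      if (!is.null(ch$unit)) get_term(o, ch$unit)
    }
    reg$characters[[cl$id]] <- ch
    local_num <- suppressWarnings(as.integer(sub("^chr:", "", cl$id)))
    if (!is.na(local_num) && local_num >= reg$next_id) reg$next_id <- local_num + 1L
  }
  reg
}
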