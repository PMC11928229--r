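# Exports: CSV (RFC 4180) for spreadsheets, TriG named-graph RDF for
# computer agents, and a template-generated narrative description for
# human readers. All three are deterministic renderings of the session,
# so the filled-state count is conserved across formats.

matrix_characters_in_tab_order <- function(m) {
  chars <- m$registry$characters
  tabs <- vapply(chars, function(ch) ch$organ_tab, character(1))
  ids <- names(chars)
  ids[order(match(tabs, unique(tabs)), seq_along(ids))]
}

cell_display_string <- function(o, cell) {
  paste(vapply(cell$states, function(st) state_display(o, st), character(1)),
        collapse = "; ")
}

#' Export a matrix to CSV
#'
#' UTF-8, comma-delimited, RFC 4180 quoting. The header row holds
#' character display names in tab order; one row per (taxon, sample);
#' multiple states in a cell are joined by `"; "`. Modifiers and
#' constraints are rendered inline in the display micro-syntax
#' `pre degree value post (certainty)`.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(m, o, path) {
  char_ids <- matrix_characters_in_tab_order(m)
  headers <- vapply(char_ids, function(cid)
    character_name(o, m$registry$characters[[cid]]), character(1))
  rows_key <- unique(t(vapply(m$cells, function(cell)
    c(cell$taxon, cell$sample), character(2))))
  if (is.null(dim(rows_key))) rows_key <- matrix(rows_key, ncol = 2L)
  if (nrow(rows_key)) {
    rows_key <- rows_key[order(rows_key[, 1L], rows_key[, 2L]), , drop = FALSE]
  }
  df <- data.frame(matrix(character(0), nrow = 0, ncol = 2L + length(char_ids)),
                   stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(rows_key))) {
    taxon <- rows_key[[i, 1L]]; sample <- rows_key[[i, 2L]]
    vals <- vapply(char_ids, function(cid) {
      cell <- m$cells[[cell_key(taxon, sample, cid)]]
      if (is.null(cell)) "" else cell_display_string(o, cell)
    }, character(1))
    out[[i]] <- c(taxon, sample, vals)
  }
  tab <- if (length(out)) as.data.frame(do.call(rbind, out),
                                        stringsAsFactors = FALSE)
         else as.data.frame(matrix(character(0), ncol = 2L + length(char_ids)),
                            stringsAsFactors = FALSE)
  names(tab) <- c("taxon", "sample", headers)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

# ---- TriG -------------------------------------------------------------------

iri_safe <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

chr_iri <- function(id) paste0("crm:", sub(":", "_", id))

#' Export a matrix as a TriG knowledge graph
#'
#' One named graph per (taxon, sample); each filled state is a node
#' carrying predicates for its character, entity, quality, value (term
#' IRI, numeric literals with a unit IRI, or an sRGB literal
#' `"rgb(r,g,b)"` plus a label literal), modifiers, constraints and
#' provenance. Raw-text states pending a term proposal export with a
#' `crm:raw_value` literal and the `to_review` class as their value. The
#' `crm:` namespace is this package's documented matrix vocabulary.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @param path Output path (`.trig`).
#' @return `path`, invisibly.
#' @export
export_trig <- function(m, o, path) {
  rows <- list()
  add <- function(graph, s, p, obj, lit = FALSE, dtype = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      graph = graph, s = s, p = p, o = obj, lit = lit, dtype = dtype,
      stringsAsFactors = FALSE)
  }
  keys <- names(m$cells)
  cells <- m$cells[order(vapply(m$cells, function(c)
    paste(c$taxon, c$sample, c$character), character(1)))]
  n_state <- 0L
  for (cell in cells) {
    graph <- sprintf("crm:g_%s_%s", iri_safe(cell$taxon), iri_safe(cell$sample))
    ch <- m$registry$characters[[cell$character]]
    for (st in cell$states) {
      n_state <- n_state + 1L
      node <- sprintf("crm:state_%04d", n_state)
      add(graph, node, "rdf:type", "crm:CharacterState")
      add(graph, node, "crm:taxon", cell$taxon, lit = TRUE)
      add(graph, node, "crm:sample", cell$sample, lit = TRUE)
      add(graph, node, "crm:character", chr_iri(cell$character))
      add(graph, node, "crm:entity", ch$entity)
      add(graph, node, "crm:quality", ch$quality)
      switch(st$kind,
        term = add(graph, node, "crm:value", st$term),
        range = {
          add(graph, node, "crm:value_low", as.character(st$low), lit = TRUE,
              dtype = "xsd:decimal")
          add(graph, node, "crm:value_high", as.character(st$high), lit = TRUE,
              dtype = "xsd:decimal")
          add(graph, node, "crm:unit", st$unit)
        },
        color = {
          if (!is.null(st$color$srgb)) {
            add(graph, node, "crm:srgb",
                sprintf("rgb(%d,%d,%d)", st$color$srgb[[1L]],
                        st$color$srgb[[2L]], st$color$srgb[[3L]]), lit = TRUE)
          }
          add(graph, node, "crm:color_label", st$color$label, lit = TRUE)
        },
        raw = {
          add(graph, node, "crm:raw_value", st$raw, lit = TRUE)
          add(graph, node, "crm:value", unname(o$roots[["to_review"]]))
        }
      )
      if (!is.null(st$certainty)) add(graph, node, "crm:certainty_modifier", st$certainty)
      if (!is.null(st$degree)) add(graph, node, "crm:degree_modifier", st$degree)
      if (!is.null(st$pre_constraint))
        add(graph, node, "crm:pre_constraint", st$pre_constraint, lit = TRUE)
      if (!is.null(st$post_constraint))
        add(graph, node, "crm:post_constraint", st$post_constraint, lit = TRUE)
      prov <- st$provenance[[1L]]
      add(graph, node, "crm:recorded_by", prov$user, lit = TRUE)
      add(graph, node, "crm:recorded_at", prov$time, lit = TRUE,
          dtype = "xsd:dateTime")
      if (!is.null(prov$raw)) add(graph, node, "crm:raw_input", prov$raw, lit = TRUE)
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(graph = character(0), s = character(0), p = character(0),
               o = character(0), lit = logical(0), dtype = character(0),
               stringsAsFactors = FALSE)
  write_trig(triples, path)
  invisible(path)
}

#' Count the state nodes of a TriG export
#' @param path A `.trig` file written by [export_trig()].
#' @return Number of `crm:CharacterState` nodes.
#' @export
count_trig_states <- function(path) {
  df <- parse_rdf(path = path)
  sum(df$p == "rdf:type" & df$o == "crm:CharacterState")
}

# ---- generated description --------------------------------------------------

default_templates <- function() {
  path <- system.file("extdata", "config", "templates.json", package = "charrec")
  if (nzchar(path)) jsonlite::read_json(path, simplifyVector = TRUE) else
    list(state = "{pre} {entity} {degree} {value} {post} {certainty}",
         state_separator = " or ", sentence_separator = "; ",
         group_format = "{tab}: {sentences}.")
}

render_template <- function(template, fields) {
  out <- template
  for (nm in names(fields)) {
    out <- gsub(paste0("{", nm, "}"), fields[[nm]] %||% "", out, fixed = TRUE)
  }
  trimws(gsub("  +", " ", out))
}

state_value_text <- function(o, st) {
  switch(st$kind,
    term = display_label(get_term(o, st$term)$label),
    range = {
      unit_lab <- display_label(get_term(o, st$unit)$label)
      if (st$low == st$high) sprintf("%g %s", st$low, unit_lab)
      else sprintf("%g–%g %s", st$low, st$high, unit_lab)
    },
    color = st$color$label,
    raw = st$raw
  )
}

#' Generate a narrative description of a taxon from the matrix
#'
#' Deterministic template rendering grouped by organ tab in registry
#' order; each filled state appears exactly once. Sentences follow the
#' configured template (default: pre-constraint, entity, degree
#' modifier, value(s), post-constraint, certainty modifier); numeric
#' ranges render as `low–high unit`, a point value collapsing the range.
#' Samples are described in sample order.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @param taxon Taxon present in the matrix.
#' @param templates Template config (see packaged
#'   `extdata/config/templates.json`).
#' @return A single character string.
#' @export
generate_description <- function(m, o, taxon, templates = default_templates()) {
  cells <- Filter(function(c) c$taxon == taxon, m$cells)
  if (!length(cells)) {
    stop_charrec(sprintf("taxon '%s' not present in the matrix", taxon),
                 class = "not_found")
  }
  samples <- sort(unique(vapply(cells, function(c) c$sample, character(1))))
  char_ids <- matrix_characters_in_tab_order(m)
  blocks <- character(0)
  for (smp in samples) {
    tabs <- list()
    for (cid in char_ids) {
      cell <- m$cells[[cell_key(taxon, smp, cid)]]
      if (is.null(cell) || !length(cell$states)) next
      ch <- m$registry$characters[[cid]]
      sentences <- vapply(cell$states, function(st) {
        render_template(templates$state, list(
          pre = st$pre_constraint,
          entity = display_label(get_term(o, ch$entity)$label),
          degree = if (!is.null(st$degree))
            display_label(get_term(o, st$degree)$label),
          value = state_value_text(o, st),
          post = st$post_constraint,
          certainty = if (!is.null(st$certainty))
            sprintf("(%s)", display_label(get_term(o, st$certainty)$label))
        ))
      }, character(1))
      sentence <- paste(sentences, collapse = templates$state_separator)
      tabs[[ch$organ_tab]] <- c(tabs[[ch$organ_tab]], sentence)
    }
    body <- vapply(names(tabs), function(tab) {
      render_template(templates$group_format, list(
        tab = tab, sentences = paste(tabs[[tab]],
                                     collapse = templates$sentence_separator)))
    }, character(1))
    blocks <- c(blocks, sprintf("%s, sample %s. %s", taxon, smp,
                                paste(body, collapse = " ")))
  }
  paste(blocks, collapse = "\n")
}

#' Write the generated description to a plain-text file
#'
#' Narrative export is plain text (and valid Markdown); a word-processor
#' binary format is deliberately out of scope.
#'
#' @param m A `cr_matrix`.
#' @param o A `carex_ontology`.
#' @param taxon Taxon to describe.
#' @param path Output `.txt`/`.md` path.
#' @return `path`, invisibly.
#' @export
export_description <- function(m, o, taxon, path) {
  writeLines(generate_description(m, o, taxon), path)
  invisible(path)
}
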