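# Shared fixtures, built once per test run. The demo ontology and
# registry are immutable under the functional API, so sharing them
# across tests is safe.

.fixture_cache <- new.env(parent = emptyenv())

demo_ontology <- function() {
  if (is.null(.fixture_cache$o)) .fixture_cache$o <- make_demo_ontology()
  .fixture_cache$o
}

demo_registry <- function() {
  if (is.null(.fixture_cache$reg)) {
    .fixture_cache$reg <- make_standard_characters(demo_ontology())
  }
  .fixture_cache$reg
}

demo_palettes <- function() {
  if (is.null(.fixture_cache$pal)) .fixture_cache$pal <- make_demo_palettes()
  .fixture_cache$pal
}

student_fixture <- function() {
  if (is.null(.fixture_cache$student)) {
    .fixture_cache$student <- make_student_task_fixture()
  }
  .fixture_cache$student
}

tid <- function(o, label) {
  t <- charrec:::term_by_label(o, label)
  stopifnot(!is.null(t))
  t$id
}

# exhaustive enumeration of all complete answer paths through a
# decision tree: the brute-force oracle for the recommender
enumerate_paths <- function(tree) {
  out <- list()
  walk <- function(node, answers, acts) {
    opts <- tree$nodes[[node]]$options
    for (ans in names(opts)) {
      a2 <- c(answers, stats::setNames(list(ans), node))
      acts2 <- c(acts, unlist(opts[[ans]]$activates))
      nxt <- opts[[ans]][["next"]]
      if (is.null(nxt)) {
        out[[length(out) + 1L]] <<- list(answers = a2, activations = acts2)
      } else {
        walk(nxt, a2, acts2)
      }
    }
  }
  walk(tree$root, list(), character(0))
  out
}

# python with rdflib serves as the independent RDF parser in oracle
# tests; resolved once
python_bin <- function() {
  if (is.null(.fixture_cache$python)) {
    p <- Sys.which("python")
    if (nzchar(p)) {
      ok <- tryCatch(system2(p, c("-c", shQuote("import rdflib")),
                             stdout = NULL, stderr = NULL) == 0L,
                     warning = function(w) FALSE, error = function(e) FALSE)
      if (!ok) p <- ""
    }
    .fixture_cache$python <- p
  }
  .fixture_cache$python
}
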