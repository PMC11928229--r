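test_that("the demo ontology loads from Turtle with all branches intact", {
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  o2 <- load_ontology(path)
  expect_gte(length(o2$terms), 50L)
  expect_length(o2$roots, 6L)
  expect_setequal(names(o2$roots),
                  c("anatomical_entity", "quality", "unit", "scope",
                    "to_review", "collection"))
})

test_that("Turtle save/load round-trips the triple set exactly", {
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  o2 <- load_ontology(path)
  expect_identical(charrec:::triple_set(charrec:::ontology_triples(o2)),
                   charrec:::triple_set(charrec:::ontology_triples(o)))
  # a second save is byte-identical
  path2 <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("a root-only graph loads as an ontology with no non-root terms", {
  o <- new_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  o2 <- load_ontology(path)
  expect_length(setdiff(names(o2$terms), unname(o2$roots)), 0L)
})

test_that("unknown predicates are preserved through a load/save cycle", {
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  extra <- sprintf("%s carex:seen_in \"FNA volume 23\" .",
                   tid(o, "caespitose"))
  writeLines(c(readLines(path), extra), path)
  o2 <- load_ontology(path)
  path2 <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o2, path2)
  expect_true(any(grepl("carex:seen_in", readLines(path2), fixed = TRUE)))
})

test_that("a dangling superclass reference fails validation on load", {
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  writeLines(c(readLines(path),
               "carex:9999999 a owl:Class ;",
               "    rdfs:label \"phantom\" ;",
               "    rdfs:subClassOf carex:8888888 ."), path)
  expect_error(load_ontology(path), class = "charrec_validation_error")
})

test_that("deprecation is serialized with a marker and replacement triple", {
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  lines <- readLines(path)
  awl <- tid(o, "awl_shaped")
  block <- grep(paste0("^", awl, " "), lines)
  expect_length(block, 1L)
  txt <- paste(lines, collapse = "\n")
  expect_match(txt, "owl:deprecated \"true\"\\^\\^xsd:boolean")
  expect_match(txt, paste0("carex:term_replaced_by ", tid(o, "subulate")),
               fixed = FALSE)
})

test_that("new terms are minted under to_review with persistent, increasing ids", {
  o <- demo_ontology()
  before <- o$minted
  res <- add_term(o, "junction between stem and sheath",
                  definition = "Where the stem meets the sheath.",
                  contributor = "userA")
  o2 <- res$ontology
  expect_identical(res$term$superclasses, unname(o2$roots[["to_review"]]))
  expect_true(res$term$id %in% names(o2$terms))
  # append-only minting log; new id strictly beyond all previous
  expect_identical(o2$minted[seq_len(nrow(before)), ], before)
  nums <- as.integer(sub("^carex:", "", o2$minted$id))
  expect_identical(nums, sort(nums))
  # the new term is serialized under to_review
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o2, path)
  expect_match(paste(readLines(path), collapse = "\n"),
               sprintf("%s a owl:Class ;\n    rdfs:label \"junction_between_stem_and_sheath\" ;\n    rdfs:subClassOf %s",
                       res$term$id, unname(o2$roots[["to_review"]])),
               fixed = TRUE)
})

test_that("adding a plural-form label attaches a warning, duplicates are rejected", {
  o <- demo_ontology()
  res <- add_term(o, "primarily pistillate inflorescence units",
                  definition = paste("Inflorescence units covered by pistillate",
                                     "flowers for more than half of their total length."),
                  contributor = "expert1")
  expect_true("plural_form" %in% vapply(res$warnings, `[[`, "", "kind"))
  expect_error(add_term(o, "caespitose"), class = "charrec_duplicate_error")
  expect_error(add_term(o, "Cespitose"), class = "charrec_duplicate_error")
})

test_that("deprecation preserves the id and notices every referencing cell", {
  fx <- student_fixture()
  o <- fx$ontology
  smooth <- tid(o, "smooth")
  res <- deprecate_term(o, smooth, tid(o, "scabrous"),
                        matrices = list(fx$matrix))
  expect_true(res$ontology$terms[[smooth]]$deprecated)
  expect_identical(res$ontology$terms[[smooth]]$id, smooth)
  # the student matrix records "smooth" once per sample
  expect_identical(nrow(res$notices), 2L)
  # three referencing cells give three notices
  m <- fx$matrix
  m <- set_state(m, o, "Carex altera", "A", "chr:0000006", "smooth", user = "u9")
  res3 <- deprecate_term(o, smooth, tid(o, "scabrous"), matrices = list(m))
  expect_identical(nrow(res3$notices), 3L)
})

test_that("deprecating against an inverse replacement raises a cycle error", {
  o <- demo_ontology()
  a <- tid(o, "scabrous"); b <- tid(o, "papillose")
  o2 <- deprecate_term(o, a, b)$ontology
  expect_error(deprecate_term(o2, b, a), class = "charrec_cycle_error")
  expect_error(deprecate_term(o, a, a), class = "charrec_cycle_error")
})

test_that("replacement chains resolve transitively to the live term", {
  o <- demo_ontology()
  live <- tid(o, "caespitose")
  expect_identical(resolve_replacement_chain(o, live), live)
  # two-step chain ends at the live color
  expect_identical(resolve_replacement_chain(o, tid(o, "glaucous_green")),
                   tid(o, "glaucous"))
  expect_identical(resolve_replacement_chain(o, tid(o, "glaucescent")),
                   tid(o, "glaucous"))
  # corrupt chain: a -> b -> a
  a <- tid(o, "scabrous"); b <- tid(o, "papillose")
  o$terms[[a]]$deprecated <- TRUE; o$terms[[a]]$replaced_by <- b
  o$terms[[b]]$deprecated <- TRUE; o$terms[[b]]$replaced_by <- a
  expect_error(resolve_replacement_chain(o, a), class = "charrec_cycle_error")
  # dead end
  o3 <- demo_ontology()
  o3$terms[[a]]$deprecated <- TRUE
  expect_error(resolve_replacement_chain(o3, a),
               class = "charrec_unresolved_deprecation_error")
})

test_that("branch listings are sorted, live-only and stable", {
  o <- demo_ontology()
  gf <- branch_of(o, tid(o, "growth_form"))
  expect_true(tid(o, "caespitose") %in% gf)
  labs <- vapply(gf, function(id) o$terms[[id]]$label, character(1))
  expect_identical(unname(labs), sort(unname(labs)))
  # leaf term
  expect_length(branch_of(o, tid(o, "caespitose")), 0L)
  # deprecated children excluded
  shape <- branch_of(o, tid(o, "shape"))
  expect_false(tid(o, "awl_shaped") %in% shape)
  color <- branch_of(o, tid(o, "color"))
  expect_false(any(c(tid(o, "glaucescent"), tid(o, "glaucous_green")) %in% color))
  # stable across consecutive calls
  expect_identical(branch_of(o, tid(o, "quality")), branch_of(o, tid(o, "quality")))
})

test_that("saved Turtle parses with an independent RDF parser", {
  py <- python_bin()
  expect_true(nzchar(py))
  o <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".ttl")
  save_ontology(o, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))",
    path), script)
  out <- system2(py, script, stdout = TRUE)
  expect_identical(as.integer(out[[1]]),
                   nrow(charrec:::ontology_triples(o)))
})
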