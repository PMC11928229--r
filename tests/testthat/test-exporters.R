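test_that("CSV export has one header and one row per taxon/sample", {
  fx <- student_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(fx$matrix, fx$ontology, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expect_identical(tab$sample, c("A", "B"))
  # re-parsing reproduces every cell's display string
  for (cell in fx$matrix$cells) {
    expect_identical(
      tab[tab$sample == cell$sample,
          character_name(fx$ontology, fx$registry$characters[[cell$character]])],
      charrec:::cell_display_string(fx$ontology, cell))
  }
})

test_that("empty matrices export a header-only CSV and a graph-free TriG", {
  m <- new_matrix(demo_registry())
  o <- demo_ontology()
  cpath <- withr::local_tempfile(fileext = ".csv")
  export_csv(m, o, cpath)
  expect_length(readLines(cpath), 1L)
  tpath <- withr::local_tempfile(fileext = ".trig")
  export_trig(m, o, tpath)
  expect_identical(count_trig_states(tpath), 0L)
  expect_false(any(grepl("\\{", readLines(tpath))))
})

test_that("values containing commas and quotes survive the CSV round trip", {
  o <- demo_ontology()
  m <- new_matrix(demo_registry(), clock = make_counter_clock())
  m <- set_state(m, o, "Carex t", "A", "chr:0000006", "smooth",
                 pre = "near base, above the \"collar\"", user = "u1")
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(m, o, path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  cell <- m$cells[[charrec:::cell_key("Carex t", "A", "chr:0000006")]]
  expect_identical(unname(unlist(tab[1, "texture of leaf"])),
                   charrec:::cell_display_string(o, cell))
  expect_match(tab[1, "texture of leaf"], "near base, above the \"collar\"",
               fixed = TRUE)
})

test_that("TriG export carries one state node per filled state", {
  fx <- student_fixture()
  path <- withr::local_tempfile(fileext = ".trig")
  export_trig(fx$matrix, fx$ontology, path)
  n_states <- sum(vapply(fx$matrix$cells, function(c) length(c$states),
                         integer(1)))
  expect_identical(count_trig_states(path), n_states)
  df <- charrec:::parse_rdf(path = path)
  # single-cell matrix: the state node's value IRI is the recorded term
  o <- fx$ontology
  m1 <- new_matrix(fx$registry, clock = make_counter_clock())
  m1 <- set_state(m1, o, "Carex uni", "A", "chr:0000001", "caespitose",
                  user = "u1")
  p1 <- withr::local_tempfile(fileext = ".trig")
  export_trig(m1, o, p1)
  d1 <- charrec:::parse_rdf(path = p1)
  expect_identical(count_trig_states(p1), 1L)
  expect_identical(d1$o[d1$p == "crm:value"], tid(o, "caespitose"))
  expect_identical(unique(d1$graph[!is.na(d1$graph)]), "crm:g_Carex_uni_A")
  # color states carry both the sRGB literal and the label literal
  srgb <- df$o[df$p == "crm:srgb"]
  labels <- df$o[df$p == "crm:color_label"]
  expect_length(srgb, 2L)
  expect_length(labels, 2L)
  expect_match(srgb, "^rgb\\(\\d+,\\d+,\\d+\\)$")
})

test_that("TriG output parses with an independent RDF parser", {
  py <- python_bin()
  expect_true(nzchar(py))
  fx <- student_fixture()
  path <- withr::local_tempfile(fileext = ".trig")
  export_trig(fx$matrix, fx$ontology, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import rdflib",
    "d = rdflib.Dataset()",
    sprintf("d.parse('%s', format='trig')", path),
    "crm = 'http://example.org/carex/matrix#'",
    "n = sum(1 for _ in d.quads((None, rdflib.RDF.type, rdflib.URIRef(crm + 'CharacterState'), None)))",
    "g = set(g for _, _, _, g in d.quads((None, None, None, None)))",
    "print(n); print(len(g))"), script)
  out <- system2(py, script, stdout = TRUE)
  expect_identical(as.integer(out[[1]]), 11L)
  expect_identical(as.integer(out[[2]]), 2L)  # one named graph per sample
})

test_that("generated descriptions are deterministic and mention every state once", {
  fx <- student_fixture()
  o <- fx$ontology
  d1 <- generate_description(fx$matrix, o, fx$taxon)
  d2 <- generate_description(fx$matrix, o, fx$taxon)
  expect_identical(d1, d2)
  expect_error(generate_description(fx$matrix, o, "Carex absentis"),
               class = "charrec_not_found_error")
  # point ranges collapse; true ranges use the en dash
  expect_match(d1, "stem 40 cm", fixed = TRUE)
  expect_match(d1, "3–5 mm", fixed = TRUE)
  # every filled state's value text appears in its sample's block
  blocks <- strsplit(d1, "\n")[[1]]
  names(blocks) <- sub("^.*sample ([A-Z])\\..*$", "\\1", blocks)
  mention_count <- 0L
  for (cell in fx$matrix$cells) {
    for (st in cell$states) {
      val <- charrec:::state_value_text(o, st)
      expect_match(blocks[[cell$sample]], val, fixed = TRUE)
      mention_count <- mention_count + 1L
    }
  }
  expect_identical(mention_count, 11L)
})

test_that("the filled-state count is conserved across all export formats", {
  fx <- student_fixture()
  o <- fx$ontology
  session_states <- sum(vapply(fx$matrix$cells, function(c) length(c$states),
                               integer(1)))
  cpath <- withr::local_tempfile(fileext = ".csv")
  export_csv(fx$matrix, o, cpath)
  tab <- utils::read.csv(cpath, check.names = FALSE, colClasses = "character")
  csv_states <- sum(vapply(unlist(tab[, -(1:2), drop = FALSE]), function(v) {
    if (!nzchar(v)) 0L else length(strsplit(v, "; ", fixed = TRUE)[[1]])
  }, integer(1)))
  tpath <- withr::local_tempfile(fileext = ".trig")
  export_trig(fx$matrix, o, tpath)
  expect_identical(csv_states, session_states)
  expect_identical(count_trig_states(tpath), session_states)
  # repeated export runs are byte-identical
  c2 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".trig")
  export_csv(fx$matrix, o, c2); export_trig(fx$matrix, o, t2)
  expect_identical(readLines(c2), readLines(cpath))
  expect_identical(readLines(t2), readLines(tpath))
})
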