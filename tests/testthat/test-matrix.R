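new_demo_matrix <- function() {
  new_matrix(demo_registry(), clock = make_counter_clock())
}

test_that("text input is resolved and preferred terms substituted with provenance", {
  o <- demo_ontology()
  m <- new_demo_matrix()
  m <- set_state(m, o, "Carex t", "A", "chr:0000001", "cespitose", user = "u1")
  st <- m$cells[[charrec:::cell_key("Carex t", "A", "chr:0000001")]]$states[[1]]
  expect_identical(st$kind, "term")
  expect_identical(st$term, tid(o, "caespitose"))
  expect_identical(st$provenance[[1]]$raw, "cespitose")
  # deprecated input is substituted by the live replacement
  m <- set_state(m, o, "Carex t", "A", "chr:0000005", "awl shaped", user = "u1")
  st2 <- m$cells[[charrec:::cell_key("Carex t", "A", "chr:0000005")]]$states[[1]]
  expect_identical(st2$term, tid(o, "subulate"))
  # unmatched text is kept raw, pending a proposal
  m <- set_state(m, o, "Carex t", "A", "chr:0000006", "gutter-shape", user = "u1")
  st3 <- m$cells[[charrec:::cell_key("Carex t", "A", "chr:0000006")]]$states[[1]]
  expect_identical(st3$kind, "raw")
  expect_true(isTRUE(st3$pending_term))
})

test_that("numeric input forms ranges with the character's unit", {
  o <- demo_ontology()
  m <- new_demo_matrix()
  m <- set_state(m, o, "Carex t", "A", "chr:0000002", 40, user = "u1")
  st <- m$cells[[charrec:::cell_key("Carex t", "A", "chr:0000002")]]$states[[1]]
  expect_identical(st[c("low", "high")], list(low = 40, high = 40))
  expect_identical(st$unit, tid(o, "cm"))
  expect_identical(charrec:::state_display(o, st), "40 cm")
  expect_error(set_state(m, o, "Carex t", "A", "chr:0000002",
                         list(low = 5, high = 3), user = "u1"),
               class = "charrec_validation_error")
  expect_error(set_state(m, o, "Carex t", "A", "chr:0000001", 40, user = "u1"),
               class = "charrec_kind_mismatch_error")
  expect_error(set_state(m, o, "Carex t", "A", "chr:0000002", "long", user = "u1"),
               class = "charrec_kind_mismatch_error")
  expect_error(set_state(m, o, "Carex t", "A", "chr:9999999", 1, user = "u1"),
               class = "charrec_not_found_error")
})

test_that("the shared-value pool aggregates across users and keeps warnings", {
  o <- demo_ontology()
  m <- new_demo_matrix()
  m <- set_state(m, o, "Carex t", "A", "chr:0000001", "caespitose", user = "u1")
  m <- set_state(m, o, "Carex t", "B", "chr:0000001", "cespitose", user = "u2")
  sv <- get_shared_values(m, "Carex t", "chr:0000001")
  expect_identical(nrow(sv), 1L)
  expect_identical(sv$count, 2L)
  expect_identical(sv$contributors, "u1;u2")
  expect_identical(nrow(get_shared_values(m, "Carex x", "chr:0000001")), 0L)

  # a reused misspelling stays on offer, with its warning attached
  for (i in 1:18) {
    m <- set_state(m, o, "Carex t", sprintf("S%02d", i), "chr:0000006",
                   "conspicious", user = sprintf("u%d", i %% 5))
  }
  sv2 <- get_shared_values(m, "Carex t", "chr:0000006")
  expect_identical(sv2$count, 18L)
  expect_match(sv2$warnings, "not in the ontology")

  # pool counts equal a brute-force recount over the cells
  counts <- table(unlist(lapply(m$cells, function(cell) {
    if (cell$taxon != "Carex t") return(NULL)
    vapply(cell$states, charrec:::state_value_key, character(1))
  })))
  for (pkey in grep("^Carex t\r", names(m$pool), value = TRUE)) {
    for (e in m$pool[[pkey]]) {
      expect_identical(e$count, as.integer(counts[[e$value_key]]))
    }
  }
})

test_that("deprecation scanning flags each affected state exactly once", {
  fx <- student_fixture()
  o <- fx$ontology
  smooth <- tid(o, "smooth")
  o2 <- deprecate_term(o, smooth, tid(o, "scabrous"))$ontology
  m <- scan_deprecated(fx$matrix, o2)
  fl <- open_flags(m)
  expect_identical(nrow(fl), 2L)
  expect_identical(unique(fl$old), smooth)
  expect_identical(unique(fl$suggested), tid(o, "scabrous"))
  # idempotent rescan
  m2 <- scan_deprecated(m, o2)
  expect_identical(m2$flags, m$flags)
  # no deprecated terms used -> no flags
  expect_identical(nrow(open_flags(scan_deprecated(fx$matrix, o))), 0L)
  # unresolved replacement chain -> flag without suggestion
  o3 <- fx$ontology
  o3$terms[[smooth]]$deprecated <- TRUE
  m3 <- scan_deprecated(fx$matrix, o3)
  fl3 <- open_flags(m3)
  expect_identical(nrow(fl3), 2L)
  expect_true(all(is.na(fl3$suggested)))
})

test_that("accepting all flags reaches the live fixed point; contests raise disputes", {
  fx <- student_fixture()
  o <- fx$ontology
  o2 <- deprecate_term(o, tid(o, "smooth"), tid(o, "scabrous"))$ontology
  m <- scan_deprecated(fx$matrix, o2)
  fl <- open_flags(m)
  for (id in fl$id) m <- accept_replacement(m, id, user = "curator")
  expect_identical(nrow(open_flags(m)), 0L)
  m_re <- scan_deprecated(m, o2)
  expect_identical(nrow(open_flags(m_re)), 0L)
  for (cell in m_re$cells) {
    for (st in cell$states) {
      if (identical(st$kind, "term")) {
        expect_false(o2$terms[[st$term]]$deprecated)
      }
    }
  }
  # provenance keeps the original raw input and the swap record
  key <- names(which(vapply(m$cells, function(c)
    c$character == "chr:0000006" && c$sample == "A", logical(1))))[[1]]
  prov <- m$cells[[key]]$states[[1]]$provenance
  expect_identical(prov[[1]]$raw, "smooth")
  expect_match(prov[[2]]$action, "replaced")
  # double-processing and contests
  expect_error(accept_replacement(m, fl$id[[1]]), class = "charrec_state_error")
  m4 <- scan_deprecated(fx$matrix, o2)
  res <- contest_deprecation(m4, open_flags(m4)$id[[1]], "the term is in wide use",
                             o2, user = "expert1")
  expect_identical(res$matrix$flags[[open_flags(m4)$id[[1]]]]$status, "contested")
  iss <- res$queue$issues[[res$issue_id]]
  expect_identical(iss$type, "deprecation_dispute")
})

test_that("the vocabulary metric matches an independent tokenizer and is order-invariant", {
  vf <- make_vocab_study_fixture()
  o <- vf$ontology
  v <- vocabulary_variation(list(vf$freehand, vf$controlled), o)
  # independent oracle: tokenize the serialized CSV exports
  oracle <- character(0)
  for (m in list(vf$freehand, vf$controlled)) {
    path <- withr::local_tempfile(fileext = ".csv")
    export_csv(m, o, path)
    tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    vals <- unlist(tab[, -(1:2), drop = FALSE])
    oracle <- c(oracle, unlist(strsplit(tolower(vals), "[^a-z0-9]+")))
  }
  oracle <- sort(unique(oracle[nzchar(oracle)]))
  expect_identical(v$words, oracle)
  # order invariance
  v_swap <- vocabulary_variation(list(vf$controlled, vf$freehand), o)
  expect_identical(v_swap$distinct_words, v$distinct_words)
  expect_error(vocabulary_variation(vf$controlled, o, baseline = 0),
               class = "charrec_domain_error")
  expect_identical(vocabulary_reduction(116, 116), 0)
})

test_that("completeness reports counts and per-cell omissions", {
  fx <- student_fixture()
  cc <- completeness_check(fx$matrix, fx$expected)
  expect_identical(cc[c("characters", "samples", "states")],
                   list(characters = 6L, samples = 2L, states = 11L))
  expect_length(cc$omissions, 0L)
  # an empty matrix omits every expected cell
  empty <- new_demo_matrix()
  cc0 <- completeness_check(empty, fx$expected)
  expect_length(cc0$omissions, nrow(fx$expected$cells))
  expect_false(cc0$complete)
  # removing one recorded state yields exactly one omission
  m1 <- fx$matrix
  key <- names(m1$cells)[[3]]
  m1$cells[[key]]$states <- list()
  cc1 <- completeness_check(m1, fx$expected)
  expect_length(cc1$omissions, 1L)
})

test_that("sessions round-trip through the JSON store", {
  fx <- student_fixture()
  o <- fx$ontology
  m <- scan_deprecated(fx$matrix,
                       deprecate_term(o, tid(o, "smooth"), tid(o, "scabrous"))$ontology)
  path <- withr::local_tempfile(fileext = ".json")
  save_matrix(m, path)
  m2 <- load_matrix(path, fx$registry, clock = make_counter_clock())
  expect_setequal(names(m2$cells), names(m$cells))
  for (k in names(m$cells)) {
    expect_identical(lapply(m2$cells[[k]]$states, charrec:::state_value_key),
                     lapply(m$cells[[k]]$states, charrec:::state_value_key))
  }
  expect_identical(length(m2$flags), length(m$flags))
  # exports from the reloaded session are byte-identical
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_csv(m, o, p1); export_csv(m2, o, p2)
  expect_identical(readLines(p1), readLines(p2))
})
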