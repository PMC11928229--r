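test_that("issues are typed, validated and coalesced on re-enqueue", {
  o <- demo_ontology()
  q <- new_issue_queue()
  r1 <- enqueue_issue(q, o, "new_term_approval", terms = tid(o, "beneath"),
                      proposed_text = "beneath", contributor = "expert2")
  r2 <- enqueue_issue(r1$queue, o, "new_term_approval",
                      terms = tid(o, "beneath"), proposed_text = "beneath",
                      contributor = "expert2")
  expect_identical(r2$id, r1$id)
  expect_identical(nrow(list_issues(r2$queue)), 1L)
  expect_error(enqueue_issue(q, o, "mystery_type", terms = tid(o, "beneath")),
               class = "charrec_validation_error")
  expect_error(enqueue_issue(q, o, "new_term_approval", terms = "carex:9999999"),
               class = "charrec_not_found_error")
})

test_that("category assignment moves a reviewed term under its superclass", {
  o <- demo_ontology()
  # a quality used as texture gets filed for re-categorization
  res <- add_term(o, "velvety", "Soft like velvet.", "expert1")
  o <- res$ontology
  q <- enqueue_issue(new_issue_queue(), o, "category_assignment",
                     terms = res$term$id)
  out <- resolve_issue(q$queue, q$id,
                       resolution("assign_superclass", term = res$term$id,
                                  superclass = tid(o, "texture")), o)
  expect_identical(out$ontology$terms[[res$term$id]]$superclasses,
                   tid(o, "texture"))
  expect_identical(out$queue$issues[[q$id]]$status, "resolved")
  expect_true(res$term$id %in% branch_of(out$ontology, tid(o, "texture")))
})

test_that("merging equivalents keeps the duplicate resolvable forever", {
  o <- demo_ontology()
  below <- tid(o, "below"); beneath <- tid(o, "beneath")
  det <- detect_equivalent_candidates(o, queue = new_issue_queue())
  id <- list_issues(det$queue)$id[[1]]
  out <- resolve_issue(det$queue, id,
                       resolution("merge_as_synonym", duplicate = beneath,
                                  survivor = below), o)
  o2 <- out$ontology
  expect_true(o2$terms[[beneath]]$deprecated)
  expect_identical(o2$terms[[beneath]]$replaced_by, below)
  expect_true("beneath" %in% o2$terms[[below]]$exact_synonyms)
  m <- match_term(o2, "beneath")
  expect_identical(m$match_kind, "exact_synonym")
  expect_identical(m$matched_term, below)
  # replacement-chain-only configuration still resolves the label
  out2 <- resolve_issue(det$queue, id,
                        resolution("merge_as_synonym", duplicate = beneath,
                                   survivor = below), o,
                        merge_keep_synonym = FALSE)
  m2 <- match_term(out2$ontology, "beneath")
  expect_identical(m2$match_kind, "deprecated_replaced")
  expect_identical(m2$suggestion, below)
  # merge direction is explicit, never inferred
  expect_error(resolve_issue(det$queue, id,
                             resolution("merge_as_synonym", duplicate = beneath),
                             o),
               class = "charrec_validation_error")
})

test_that("deprecation disputes can revoke the deprecation and withdraw flags", {
  fx <- student_fixture()
  o <- fx$ontology
  smooth <- tid(o, "smooth")
  o2 <- deprecate_term(o, smooth, tid(o, "scabrous"))$ontology
  m <- scan_deprecated(fx$matrix, o2)
  expect_identical(nrow(open_flags(m)), 2L)
  ct <- contest_deprecation(m, open_flags(m)$id[[1]], "widely used", o2)
  out <- resolve_issue(ct$queue, ct$issue_id,
                       resolution("revoke_deprecation", term = smooth), o2,
                       matrices = list(ct$matrix))
  expect_false(out$ontology$terms[[smooth]]$deprecated)
  expect_null(out$ontology$terms[[smooth]]$replaced_by)
  m2 <- out$matrices[[1]]
  expect_identical(nrow(open_flags(m2)), 0L)
  statuses <- vapply(m2$flags, `[[`, "", "status")
  expect_true(all(statuses == "withdrawn"))
  # upholding keeps the term deprecated
  ct2 <- contest_deprecation(scan_deprecated(fx$matrix, o2),
                             open_flags(scan_deprecated(fx$matrix, o2))$id[[1]],
                             "second dispute", o2)
  out2 <- resolve_issue(ct2$queue, ct2$issue_id,
                        resolution("uphold_deprecation", term = smooth), o2)
  expect_true(out2$ontology$terms[[smooth]]$deprecated)
})

test_that("rejected resolutions leave the ontology and the issue untouched", {
  o <- demo_ontology()
  res <- add_term(o, "felty", NULL, "expert1")
  o <- res$ontology
  q <- enqueue_issue(new_issue_queue(), o, "definition_approval",
                     terms = res$term$id)
  before <- charrec:::triple_set(charrec:::ontology_triples(o))
  expect_error(resolve_issue(q$queue, q$id,
                             resolution("approve_definition",
                                        term = res$term$id, text = "  "), o),
               class = "charrec_validation_error")
  expect_identical(charrec:::triple_set(charrec:::ontology_triples(o)), before)
  expect_identical(q$queue$issues[[q$id]]$status, "open")
  # type-incompatible action
  expect_error(resolve_issue(q$queue, q$id,
                             resolution("revoke_deprecation", term = res$term$id),
                             o),
               class = "charrec_validation_error")
  # closed issues cannot be re-resolved
  ok <- resolve_issue(q$queue, q$id,
                      resolution("approve_definition", term = res$term$id,
                                 text = "Felt-like surface."), o)
  expect_error(resolve_issue(ok$queue, q$id,
                             resolution("approve_definition",
                                        term = res$term$id, text = "again"),
                             ok$ontology),
               class = "charrec_state_error")
})

test_that("ontology diffs classify into new, deprecated and modified notices", {
  o <- demo_ontology()
  expect_identical(nrow(emit_update_notices(o, o)$notices), 0L)
  o2 <- add_term(o, "first new", NULL)$ontology
  o2 <- add_term(o2, "second new", NULL)$ontology
  o2$terms[[tid(o, "acute")]]$definition <- "Tapering to a sharp point."
  n <- emit_update_notices(o, o2)$notices
  expect_identical(as.integer(table(factor(n$category,
    levels = c("new_terms", "deprecated_terms", "modified_terms")))),
    c(2L, 0L, 1L))
  o3 <- deprecate_term(o, tid(o, "scabrous"), tid(o, "papillose"))$ontology
  n3 <- emit_update_notices(o, o3)$notices
  expect_identical(n3$category, "deprecated_terms")
  expect_identical(n3$term, tid(o, "scabrous"))
})

test_that("queues persist as an append-only JSON-lines log", {
  o <- demo_ontology()
  q <- new_issue_queue()
  r <- enqueue_issue(q, o, "new_term_approval", terms = tid(o, "beneath"),
                     proposed_text = "beneath", form_flags = "plural_form")
  q <- r$queue
  r2 <- enqueue_issue(q, o, "deprecation_dispute", terms = tid(o, "awl_shaped"),
                      proposed_text = "still needed")
  q <- r2$queue
  path <- withr::local_tempfile(fileext = ".jsonl")
  save_queue(q, path)
  expect_length(readLines(path), 2L)
  q2 <- load_queue(path)
  expect_identical(list_issues(q2), list_issues(q))
  expect_identical(q2$issues[[r$id]]$form_flags, "plural_form")
})
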