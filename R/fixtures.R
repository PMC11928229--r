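# Deterministic fixture generation: a miniature sedge ontology with all
# synonym tiers and a deprecation chain, the recommended character set, a
# decision tree, the student recording task (6 characters x 2 samples,
# 11 states) and a two-matrix vocabulary-variation study. Generation is
# a pure function of the fixture spec, so fixtures regenerate
# byte-identically.

#' Fixture generation spec
#'
#' @param seed Integer recorded with the fixture (generation itself is
#'   deterministic).
#' @param n_terms Minimum number of ontology terms; filler entity terms
#'   are added beyond the curated inventory if needed.
#' @param include_deprecations Include the deprecated terms and their
#'   replacement chains.
#' @param standard_set_size Number of characters in the recommended core
#'   set (default 6).
#' @param samples Number of specimen samples in the student task
#'   (default 2).
#' @param target_states Expected number of recorded states in the
#'   student task (default 11: six for the first sample, five for each
#'   further sample — growth form is recorded once per taxon).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 50L, include_deprecations = TRUE,
                         standard_set_size = 6L, samples = 2L,
                         target_states = NULL) {
  if (n_terms <= 0L || standard_set_size <= 0L || samples <= 0L) {
    stop_charrec("fixture counts must be positive", class = "validation")
  }
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 include_deprecations = isTRUE(include_deprecations),
                 standard_set_size = as.integer(standard_set_size),
                 samples = as.integer(samples),
                 target_states = target_states %||% (6L + 5L * (samples - 1L))),
            class = "fixture_spec")
}

#' A deterministic counter clock for reproducible sessions
#' @param start ISO-8601 UTC start time.
#' @return A zero-argument function returning successive timestamps one
#'   second apart.
#' @export
make_counter_clock <- function(start = "2022-04-01T00:00:00Z") {
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  function() {
    out <- format(t0 + env$i, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    env$i <- env$i + 1L
    out
  }
}

#' Build the demonstration ontology
#'
#' A ~75-term miniature of a sedge phenotype ontology: six root
#' branches, anatomical entities (stem, leaf, inflorescence, perigynium
#' parts and measurement landmarks such as the junction between stem and
#' rhizome), quality subgroups (growth form, shape, color, texture,
#' position, modifiers, length/width), all four synonym/annotation tiers
#' (caespitose has exact synonym "cespitose"; acute has not-recommended
#' synonym "acutish"; bright has broad synonym "light"), a one-step
#' deprecation (awl_shaped replaced by subulate) and a two-step
#' replacement chain (glaucous_green -> glaucescent -> glaucous), a
#' recommended-character collection, units, scopes, and one
#' user-contributed term under review ("beneath").
#'
#' @param spec A [fixture_spec()].
#' @return A `carex_ontology`.
#' @export
make_demo_ontology <- function(spec = fixture_spec()) {
  o <- new_ontology()
  ids <- new.env(parent = emptyenv())
  for (nm in names(o$roots)) ids[[nm]] <- unname(o$roots[[nm]])
  put <- function(label, parent, definition = NULL) {
    res <- mint_term(o, label, definition = definition,
                     superclasses = ids[[parent]])
    o <<- res$ontology
    ids[[label]] <- res$term$id
    res$term$id
  }

  # anatomical entities
  for (e in c("plant", "stem", "culm", "rhizome", "stem_base",
              "junction_between_stem_and_rhizome", "flowering_stem",
              "leaf", "leaf_blade", "leaf_sheath", "leaf_apex",
              "inflorescence", "inflorescence_unit", "terminal_spike",
              "perigynium", "perigynium_apex", "perigynium_beak", "achene",
              "scale", "margin", "surface")) {
    put(e, "anatomical_entity",
        definition = sprintf("The %s of the plant.", display_label(e)))
  }
  # quality subgroups
  for (q in c("growth_form", "shape", "color", "length", "width",
              "texture", "surface_feature", "pubescence", "position",
              "modifier")) {
    put(q, "quality")
  }
  put("caespitose", "growth_form",
      definition = "Growing in dense tufts from short rhizomes.")
  put("rhizomatous", "growth_form",
      definition = "Spreading by elongate rhizomes.")
  put("stoloniferous", "growth_form", definition = "Producing stolons.")
  for (s in c("subulate", "acute", "obtuse", "lanceolate", "ovate",
              "gutter_shaped", "orbicular", "trigonous")) {
    put(s, "shape", definition = sprintf("%s in outline.", display_label(s)))
  }
  for (cc in c("brown", "yellow_brown", "yellow_green", "green", "red",
               "bright", "dark", "glaucous")) {
    put(cc, "color")
  }
  for (tx in c("smooth", "scabrous", "papillose")) {
    put(tx, "texture", definition = sprintf("Surface %s.", display_label(tx)))
  }
  for (p in c("below", "distal", "proximal")) put(p, "position")
  for (mdf in c("usually", "slightly", "strongly", "uncertain", "probably")) {
    put(mdf, "modifier")
  }
  put("cm", "unit"); put("mm", "unit")
  put("per_plant", "scope"); put("per_culm", "scope")
  put("carex_standard_character_set", "collection",
      definition = "The recommended core characters for the group.")
  # a user-contributed term awaiting review, equivalent to "below"
  put("beneath", "to_review")
  o$terms[[ids[["beneath"]]]]$contributor <- "expert2"

  # synonym tiers
  o$terms[[ids[["caespitose"]]]]$exact_synonyms <- "cespitose"
  o$terms[[ids[["acute"]]]]$not_recommended_synonyms <- "acutish"
  o$terms[[ids[["bright"]]]]$broad_synonyms <- "light"
  o$terms[[ids[["plant"]]]]$cross_refs <- "PO:0000003"
  o$terms[[ids[["caespitose"]]]]$elucidation <-
    "https://example.org/illustrations/caespitose.png"

  if (spec$include_deprecations) {
    put("awl_shaped", "shape")
    o <- deprecate_term(o, ids[["awl_shaped"]], ids[["subulate"]])$ontology
    put("glaucescent", "color")
    put("glaucous_green", "color")
    o <- deprecate_term(o, ids[["glaucescent"]], ids[["glaucous"]])$ontology
    o <- deprecate_term(o, ids[["glaucous_green"]], ids[["glaucescent"]])$ontology
  }

  # property assertions
  o <- assert_property(o, ids[["length"]], "measured_from", ids[["stem_base"]])
  o <- assert_property(o, ids[["length"]], "measured_to",
                       ids[["junction_between_stem_and_rhizome"]])
  o <- assert_property(o, ids[["length"]], "measured_exclude",
                       ids[["inflorescence"]])
  o <- assert_property(o, ids[["width"]], "measured_at", ids[["leaf_blade"]])
  o <- assert_property(o, ids[["leaf_blade"]], "maybe_part_of", ids[["leaf"]])
  o <- assert_property(o, ids[["stem"]], "join_with", ids[["rhizome"]])
  o <- assert_property(o, ids[["growth_form"]], "in_collection",
                       ids[["carex_standard_character_set"]])

  # filler entities up to the requested term count
  n_fill <- spec$n_terms - length(o$terms)
  if (n_fill > 0L) {
    for (i in seq_len(n_fill)) put(sprintf("bract_%02d", i), "anatomical_entity")
  }
  validate_ontology(o)
  o
}

fixture_term <- function(o, label) {
  t <- term_by_label(o, label)
  if (is.null(t)) {
    stop_charrec(sprintf("fixture ontology lacks term '%s'", label),
                 class = "not_found")
  }
  t$id
}

#' Build the standard character registry for the demo ontology
#'
#' Six recommended core characters (growth form, stem length, leaf-blade
#' width, leaf-sheath color, perigynium-apex shape, leaf texture) plus
#' three specialist characters used by the decision tree, including a
#' cross-section-shape character carrying a distance constraint
#' (anchor = flowering stem, magnitude 10% below).
#'
#' @param o The demo ontology from [make_demo_ontology()].
#' @param spec A [fixture_spec()]; `standard_set_size` of the six core
#'   characters are marked recommended.
#' @return A `chr_registry`.
#' @export
make_standard_characters <- function(o, spec = fixture_spec()) {
  reg <- new_registry()
  id <- function(label) fixture_term(o, label)
  rec <- function(k) k <= spec$standard_set_size
  r <- define_categorical_character(o, reg, id("plant"), id("growth_form"),
                                    organ_tab = "habit", recommended = rec(1L))
  reg <- r$registry
  r <- define_numerical_character(o, reg, id("stem"), id("length"),
         landmark_spec(from = id("stem_base"),
                       to = id("junction_between_stem_and_rhizome")),
         unit = id("cm"), scope = id("per_culm"), organ_tab = "stem",
         recommended = rec(2L))
  reg <- r$registry
  r <- define_numerical_character(o, reg, id("leaf_blade"), id("width"),
         landmark_spec(at = id("leaf_blade")), unit = id("mm"),
         constraints = list(constraint_clause("positional", "at mid-length",
                                              anchor = id("leaf_blade"))),
         organ_tab = "leaf", recommended = rec(3L))
  reg <- r$registry
  r <- define_categorical_character(o, reg, id("leaf_sheath"), id("color"),
                                    organ_tab = "leaf", recommended = rec(4L))
  reg <- r$registry
  r <- define_categorical_character(o, reg, id("perigynium_apex"), id("shape"),
                                    organ_tab = "perigynium",
                                    recommended = rec(5L))
  reg <- r$registry
  r <- define_categorical_character(o, reg, id("leaf"), id("texture"),
                                    organ_tab = "leaf", recommended = rec(6L))
  reg <- r$registry
  # specialist characters reached through the decision tree
  r <- define_numerical_character(o, reg, id("inflorescence_unit"), id("length"),
         landmark_spec(at = id("inflorescence_unit")), unit = id("mm"),
         organ_tab = "inflorescence")
  reg <- r$registry
  r <- define_categorical_character(o, reg, id("inflorescence_unit"), id("shape"),
                                    organ_tab = "inflorescence")
  reg <- r$registry
  r <- define_categorical_character(o, reg, id("stem"), id("shape"),
         constraints = list(constraint_clause("distance", "at 10% below flowering stem",
                                              anchor = id("flowering_stem"),
                                              magnitude = 0.10, unit = "ratio",
                                              direction = "below")),
         organ_tab = "stem")
  reg <- r$registry
  reg
}

#' Build the demonstration decision tree
#'
#' Five question nodes; inflorescence-unit characters are activated only
#' on the "branched" path, so answering "unbranched" prunes them from
#' the recommendation.
#'
#' @return A `decision_tree`.
#' @export
make_demo_tree <- function() {
  tree <- list(
    root = "inflorescence",
    nodes = list(
      inflorescence = list(
        question = "Is the inflorescence branched?",
        options = list(
          branched = list("next" = "units", activates = list()),
          unbranched = list("next" = "spike", activates = list())
        )),
      units = list(
        question = "How many inflorescence units are there?",
        options = list(
          several = list("next" = "beak",
                         activates = list("chr:0000007", "chr:0000008")),
          one = list("next" = "beak", activates = list("chr:0000008"))
        )),
      spike = list(
        question = "Is the terminal spike solitary?",
        options = list(
          yes = list("next" = "cross_section", activates = list()),
          no = list("next" = "cross_section", activates = list())
        )),
      beak = list(
        question = "Is a perigynium beak present?",
        options = list(
          yes = list("next" = NULL, activates = list("chr:0000009")),
          no = list("next" = NULL, activates = list())
        )),
      cross_section = list(
        question = "Record the stem cross-section shape?",
        options = list(
          yes = list("next" = NULL, activates = list("chr:0000009")),
          no = list("next" = NULL, activates = list())
        ))
    )
  )
  validate_decision_tree(tree)
  structure(tree, class = "decision_tree")
}

#' Packaged demonstration palettes
#' @return Named list of palettes (brown, yellow-brown, yellow-green,
#'   green, red).
#' @export
make_demo_palettes <- function() {
  load_palettes()
}

#' Build the student recording task
#'
#' Emulates the classroom task: one taxon, two specimen samples, the six
#' recommended characters, eleven recorded states (growth form is
#' recorded once per taxon; every other character once per sample),
#' entered by two users so the shared-value pool is exercised. The
#' matrix uses a counter clock, so regeneration is byte-identical.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `ontology`, `registry`, `tree`, `palettes`,
#'   `matrix`, `taxon` and `expected` (the task sheet for
#'   [completeness_check()]).
#' @export
make_student_task_fixture <- function(spec = fixture_spec()) {
  o <- make_demo_ontology(spec)
  reg <- make_standard_characters(o, spec)
  palettes <- make_demo_palettes()
  m <- new_matrix(reg, clock = make_counter_clock())
  taxon <- "Carex demonstrativa"
  samples <- LETTERS[seq_len(spec$samples)]
  users <- c("S101", "S102")
  yb <- palettes[["yellow-brown"]]

  sheet <- list()
  note <- function(smp, chr) {
    sheet[[length(sheet) + 1L]] <<- data.frame(
      taxon = taxon, sample = smp, character = chr, n_states = 1L,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(samples)) {
    smp <- samples[[k]]
    user <- users[[(k - 1L) %% length(users) + 1L]]
    if (k == 1L) {
      # growth form: recorded once per taxon, on the first sample;
      # entered as "cespitose" to exercise preferred-term substitution
      m <- set_state(m, o, taxon, smp, "chr:0000001", "cespitose", user = user)
      note(smp, "chr:0000001")
    }
    m <- set_state(m, o, taxon, smp, "chr:0000002",
                   if (k == 1L) 40 else 38, user = user)
    note(smp, "chr:0000002")
    m <- set_state(m, o, taxon, smp, "chr:0000003",
                   list(low = 3, high = if (k == 1L) 5 else 4),
                   user = user)
    note(smp, "chr:0000003")
    m <- set_state(m, o, taxon, smp, "chr:0000004",
                   pick_color(yb, if (k == 1L) "light yellow-brown"
                              else "dark yellow-brown"),
                   user = user)
    note(smp, "chr:0000004")
    m <- set_state(m, o, taxon, smp, "chr:0000005",
                   if (k == 1L) "acutish" else "obtuse",
                   degree = if (k == 1L) fixture_term(o, "slightly"),
                   certainty = if (k == 2L) fixture_term(o, "uncertain"),
                   user = user)
    note(smp, "chr:0000005")
    m <- set_state(m, o, taxon, smp, "chr:0000006", "smooth",
                   post = if (k == 1L) "throughout", user = user)
    note(smp, "chr:0000006")
  }
  expected <- list(characters = 6L, samples = spec$samples,
                   states = spec$target_states,
                   cells = do.call(rbind, sheet))
  list(ontology = o, registry = reg, tree = make_demo_tree(),
       palettes = palettes, matrix = m, taxon = taxon, expected = expected)
}

# ---- vocabulary-variation study fixture -------------------------------------

# Freehand (spreadsheet-style) phrasings of the task values: many
# spelling, plural and wording variants of the same concepts.
freehand_vocabulary <- function() {
  base <- c(
    "densely tufted", "loosely tufted", "tufted habit", "cespitose clumps",
    "caespitose tussocks", "forming tussocks", "mat forming", "matted",
    "creeping rootstock", "long creeping rhizomes", "short rhizomatous",
    "stoloniferous runners", "culms erect", "culms arching", "stems upright",
    "stems spreading", "about forty centimeters", "roughly 40cm tall",
    "approx 400 mm", "fifteen inches high", "blades narrow", "blades narrowish",
    "leaf blade linear", "leaves grasslike", "foliage grass like",
    "sheaths brownish", "sheath pale straw", "sheathes tan colored",
    "light yellowbrown", "yellowish brown tinge", "stramineous throughout",
    "beaks abruptly acutish", "apex sharply pointed", "apexes blunt",
    "tips roundedish", "summit obtusish", "texture smoothish",
    "feels glabrous", "surfaces glabrate", "minutely roughened margins",
    "margin scabrellous", "edges serrulate above", "papillae scattered beneath",
    "somewhat glaucousgreen", "bluish green cast", "greyish foliage",
    "conspicious veins", "nerves lanceloid", "gutter-shape channel",
    "v shaped groove", "widest near middle", "circa 3-5mm wide",
    "three to five millimetres", "perhaps wider", "maybe narrower",
    "unclear borderline", "variable overall")
  # the freehand pool of the emulated study holds 116 distinct tokens
  utils::head(unique(unlist(strsplit(tolower(base), "[^a-z0-9]+"))), 116L)
}

controlled_vocabulary_states <- function() {
  list(
    list(chr = "chr:0000001", value = "caespitose"),
    list(chr = "chr:0000001", value = "rhizomatous"),
    list(chr = "chr:0000005", value = "acute"),
    list(chr = "chr:0000005", value = "obtuse"),
    list(chr = "chr:0000005", value = "lanceolate"),
    list(chr = "chr:0000005", value = "subulate"),
    list(chr = "chr:0000005", value = "orbicular"),
    list(chr = "chr:0000006", value = "smooth"),
    list(chr = "chr:0000006", value = "scabrous"),
    list(chr = "chr:0000006", value = "papillose"),
    list(chr = "chr:0000004", value = "brown"),
    list(chr = "chr:0000004", value = "yellow brown"),
    list(chr = "chr:0000004", value = "yellow green"),
    list(chr = "chr:0000004", value = "glaucous"),
    list(chr = "chr:0000004", value = "dark"),
    list(chr = "chr:0000004", value = "bright"),
    list(chr = "chr:0000004", value = "red"),
    list(chr = "chr:0000002", value = 40),
    list(chr = "chr:0000002", value = 38),
    list(chr = "chr:0000003", value = list(low = 3, high = 5)),
    list(chr = "chr:0000003", value = list(low = 2, high = 4)),
    list(chr = "chr:0000001", value = "stoloniferous"),
    list(chr = "chr:0000005", value = "ovate"),
    list(chr = "chr:0000005", value = "trigonous"),
    list(chr = "chr:0000005", value = "gutter shaped")
  )
}

#' Build the vocabulary-variation study matrices
#'
#' Two matrices recording the same task: a freehand matrix whose values
#' are unconstrained phrasings (spelling variants, plurals, synonyms and
#' hedges) and a controlled matrix restricted to ontology terms and
#' numeric ranges. The freehand vocabulary pools 116 distinct word
#' tokens; the controlled vocabulary pools 30 — the study conditions for
#' the vocabulary-variation metric.
#'
#' @param spec A [fixture_spec()].
#' @return List with `ontology`, `registry`, `freehand` and `controlled`
#'   matrices.
#' @export
make_vocab_study_fixture <- function(spec = fixture_spec()) {
  o <- make_demo_ontology(spec)
  reg <- make_standard_characters(o, spec)
  taxon <- "Carex demonstrativa"

  freehand <- new_matrix(reg, clock = make_counter_clock())
  words <- freehand_vocabulary()
  # distribute the freehand tokens over the categorical cells as raw
  # free-text values, five words at a time
  target_cells <- expand.grid(
    sample = sprintf("S%02d", 1:8),
    chr = c("chr:0000001", "chr:0000004", "chr:0000005", "chr:0000006"),
    stringsAsFactors = FALSE)
  i <- 1L
  k <- 1L
  while (i <= length(words)) {
    j <- min(i + 4L, length(words))
    phrase <- paste(words[i:j], collapse = " ")
    cellrow <- target_cells[(k - 1L) %% nrow(target_cells) + 1L, ]
    freehand <- set_state(freehand, o, taxon, cellrow$sample, cellrow$chr,
                          phrase, user = sprintf("S%03d", 100 + (k %% 16)),
                          accept_suggestion = FALSE)
    i <- j + 1L
    k <- k + 1L
  }

  controlled <- new_matrix(reg, clock = make_counter_clock())
  for (k in seq_along(controlled_vocabulary_states())) {
    st <- controlled_vocabulary_states()[[k]]
    controlled <- set_state(controlled, o, taxon, sprintf("S%02d", (k %% 4) + 1L),
                            st$chr, st$value,
                            user = sprintf("S%03d", 100 + (k %% 16)))
  }
  list(ontology = o, registry = reg, freehand = freehand,
       controlled = controlled)
}

# ---- randomized fixtures for property suites --------------------------------

#' A randomized small matrix session over the demo ontology
#'
#' Used by the round-trip property suites: records a random subset of
#' characters and samples with randomly drawn term, range and color
#' values under the given seed.
#'
#' @param seed Integer seed.
#' @param o,reg Optional prebuilt demo ontology/registry (rebuilt if
#'   omitted).
#' @return List with `ontology`, `registry`, `matrix`, `taxon`.
#' @export
random_matrix_fixture <- function(seed, o = NULL, reg = NULL) {
  if (is.null(o)) o <- make_demo_ontology()
  if (is.null(reg)) reg <- make_standard_characters(o)
  palettes <- make_demo_palettes()
  set.seed(seed)
  m <- new_matrix(reg, clock = make_counter_clock())
  taxon <- sprintf("Carex random%03d", seed %% 1000L)
  samples <- LETTERS[seq_len(sample(1:3, 1L))]
  shapes <- c("acute", "obtuse", "lanceolate", "ovate", "subulate")
  textures <- c("smooth", "scabrous", "papillose")
  growth <- c("caespitose", "rhizomatous", "stoloniferous")
  pal <- palettes[[sample(names(palettes), 1L)]]
  for (smp in samples) {
    for (cid in names(reg$characters)) {
      if (stats::runif(1) < 0.35) next
      ch <- reg$characters[[cid]]
      if (ch$kind == "numerical") {
        lo <- round(stats::runif(1, 1, 50), 1)
        hi <- lo + round(stats::runif(1, 0, 10), 1)
        m <- set_state(m, o, taxon, smp, cid, list(low = lo, high = hi),
                       user = sample(c("u1", "u2"), 1L))
      } else if (stats::runif(1) < 0.2) {
        col <- pal$colors[[sample(seq_along(pal$colors), 1L)]]
        m <- set_state(m, o, taxon, smp, cid, pick_color(pal, col$label),
                       user = sample(c("u1", "u2"), 1L))
      } else {
        value <- sample(c(shapes, textures, growth), 1L)
        m <- set_state(m, o, taxon, smp, cid, value,
                       pre = if (stats::runif(1) < 0.2) "near base",
                       post = if (stats::runif(1) < 0.2) "when mature",
                       user = sample(c("u1", "u2"), 1L))
      }
    }
  }
  list(ontology = o, registry = reg, matrix = m, taxon = taxon)
}

#' Materialize every fixture to a directory
#'
#' Writes the demo ontology (Turtle), character registry (JSON),
#' decision tree (JSON), student session (JSON) and its CSV/TriG/text
#' exports.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [fixture_spec()].
#' @return Named character vector of written paths, invisibly.
#' @export
make_all_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_student_task_fixture(spec)
  paths <- c(
    ontology = file.path(dir, "demo_ontology.ttl"),
    characters = file.path(dir, "characters.json"),
    tree = file.path(dir, "decision_tree.json"),
    session = file.path(dir, "student_session.json"),
    csv = file.path(dir, "student_matrix.csv"),
    trig = file.path(dir, "student_matrix.trig"),
    description = file.path(dir, "student_description.txt")
  )
  save_ontology(fx$ontology, paths[["ontology"]])
  export_characters(fx$registry, paths[["characters"]])
  jsonlite::write_json(unclass(fx$tree), paths[["tree"]], auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  save_matrix(fx$matrix, paths[["session"]])
  export_csv(fx$matrix, fx$ontology, paths[["csv"]])
  export_trig(fx$matrix, fx$ontology, paths[["trig"]])
  export_description(fx$matrix, fx$ontology, fx$taxon, paths[["description"]])
  invisible(paths)
}
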