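# JSON interchange: redaction, inclusion rules, severed parents, round trips.

make_exportable_db <- function() {
  db <- make_lab_db()
  l1 <- create_line(db, "donor", "alice", "Arabidopsis thaliana",
                    ecotype = "Col-0", origin = "own transformation")
  add_feature(db, l1$id, "TRANSGENESIS", "Pro35S:GUS", gene = "uidA",
              mutation_method = "T-DNA", sequence = "ATGGTCCGT",
              selectable_resistance = "Kanamycin", agro_strain = "GV3101",
              genotyping_protocol = "primers fwd/rev, 58C",
              protocol_attachments = list(attachment("gel.txt", "lane1 lane2",
                                                     "text/plain")))
  ch <- mutagenize_line(db, l1$id,
                        list(category = "ENDOGENOUS", designation = "ems-7",
                             mutation_method = "EMS", sequence = "ATGAAA"),
                        name = "derived")
  p <- add_plant(db, ch$id, "mother-1", generation_label = "T2",
                 notebook_ref = "NB-77-p3", person = "bob",
                 attachments = list(attachment("leaf.txt", "photo bytes")))
  add_seed_batch(db, ch$id, "harvest-A", generation_label = "T3",
                 mother_plant = p$id, harvest_date = "2026-03-01",
                 storage_place = "box-A-07", notebook_ref = "NB-77-s1",
                 person = "bob")
  add_seed_batch(db, ch$id, "harvest-B", generation_label = "T3",
                 storage_place = "box-A-08", notebook_ref = "NB-77-s2",
                 person = "alice")
  set_mta(db, ch$id, TRUE, "MTA-secret recipient X, freezer 4")
  db
}

sl_id <- function(db, name) {
  for (l in db$lines) if (identical(l$name, name)) return(l$id)
  stop("no line ", name)
}

exported_batch_ids <- function(db, line) {
  id <- sl_id(db, line)
  vapply(Filter(function(b) identical(b$line, id), db$batches),
         `[[`, integer(1), "system_id")
}

test_that("export includes requested batches plus their mother plants", {
  db <- make_exportable_db()
  sids <- exported_batch_ids(db, "derived")
  doc <- export_line(db, "derived", batches = sids)
  expect_length(doc$seed_batches, 2L)
  expect_length(doc$mother_plants, 1L)
  expect_identical(doc$mother_plants[[1]]$personal_identifier, "mother-1")
  expect_identical(doc$seed_batches[[1]]$mother_plant, 1L)
  expect_null(doc$seed_batches[[2]]$mother_plant)

  # a foreign batch is refused
  other <- create_line(db, "other", "alice", "Oryza sativa")
  fb <- add_seed_batch(db, other$id, "x")
  expect_error(export_line(db, "derived", batches = fb$system_id),
               class = "seedledger_consistency_error")
})

test_that("exports preserve the MTA flag but redact every sensitive field", {
  db <- make_exportable_db()
  doc <- export_line(db, "derived", batches = exported_batch_ids(db, "derived"))
  expect_true(doc$line$mta$protected)
  expect_identical(doc$line$mta$details, "")

  path <- withr::local_tempfile(fileext = ".json")
  write_interchange(doc, path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  sensitive <- c("alice", "bob",                 # person names
                 "NB-77-p3", "NB-77-s1", "NB-77-s2",  # notebook references
                 "box-A-07", "box-A-08",         # storage places
                 "MTA-secret")                   # MTA details
  for (s in sensitive) {
    expect_false(grepl(s, txt, fixed = TRUE), label = sprintf("leak of '%s'", s))
  }
  # non-sensitive content is present
  expect_true(grepl("Pro35S:GUS", txt, fixed = TRUE))
  expect_true(grepl("harvest-A", txt, fixed = TRUE))
})

test_that("randomized fixtures never leak their sensitive-value set", {
  db <- generate_fixture(4, 8, p_mta = 0.9, seed = 61)
  sensitive <- c(sprintf("member%02d", 1:5),
                 unlist(lapply(db$batches, function(b) {
                   c(b$storage_place, b$notebook_ref)
                 })),
                 unlist(lapply(db$plants, `[[`, "notebook_ref")),
                 unlist(lapply(db$lines, function(l) {
                   if (nzchar(l$mta$details)) l$mta$details
                 })))
  sensitive <- sensitive[nzchar(sensitive)]
  for (id in names(db$lines)) {
    sids <- vapply(Filter(function(b) identical(b$line, id), db$batches),
                   `[[`, integer(1), "system_id")
    doc <- export_line(db, id, batches = sids)
    txt <- jsonlite::toJSON(unclass(doc), auto_unbox = TRUE)
    for (s in sensitive) {
      expect_false(grepl(s, txt, fixed = TRUE),
                   label = sprintf("line %s leaks '%s'", id, s))
    }
  }
})

test_that("import severs parents, owns all features, keeps provenance", {
  db <- make_exportable_db()
  sids <- exported_batch_ids(db, "derived")
  doc <- export_line(db, "derived", batches = sids)
  path <- withr::local_tempfile(fileext = ".json")
  write_interchange(doc, path)

  expect_error(import_line(db, read_interchange(path), new_name = ""),
               class = "seedledger_validation_error")
  suppressWarnings(
    imp <- import_line(db, read_interchange(path), new_name = "guest-line",
                       person = "alice")
  )
  expect_identical(imp$creation_mode, "IMPORT")
  expect_length(imp$parents, 0L)

  tab <- effective_features(db, imp$id)
  expect_false(any(tab$inherited))             # all features owned
  expect_setequal(tab$designation, c("Pro35S:GUS", "ems-7"))
  expect_true("from donor" %in% tab$origin_label)  # provenance text survives

  # genealogy image stored as a file from source
  files <- datasheet(db, imp$id)$general_information$files_from_source
  expect_true("genealogy.gv" %in% files)

  # batch identifiers, generations, attachments round trip byte-exactly
  imp_batches <- Filter(function(b) identical(b$line, imp$id), db$batches)
  expect_setequal(vapply(imp_batches, `[[`, character(1), "personal_identifier"),
                  c("harvest-A", "harvest-B"))
  expect_setequal(vapply(imp_batches, `[[`, character(1), "generation_label"),
                  c("T3", "T3"))
  src_feature <- Filter(function(f) f$designation == "Pro35S:GUS" &&
                          identical(f$origin_line, imp$id), db$features)[[1]]
  expect_identical(src_feature$sequence, "ATGGTCCGT")
  expect_identical(src_feature$protocol_attachments[[1]]$content,
                   charToRaw("lane1 lane2"))
  imp_plants <- Filter(function(p) identical(p$line, imp$id), db$plants)
  expect_identical(imp_plants[[1]]$attachments[[1]]$content,
                   charToRaw("photo bytes"))

  # redacted fields arrive empty
  expect_identical(imp_batches[[1]]$storage_place, "")
  expect_identical(imp_batches[[1]]$notebook_ref, "")
  expect_identical(imp$mta$protected, TRUE)
  expect_identical(imp$mta$details, "")

  # re-import under another name: two independent lines, no dedup
  suppressWarnings(
    imp2 <- import_line(db, read_interchange(path), new_name = "guest-line-2")
  )
  expect_false(identical(imp2$id, imp$id))
  expect_identical(nrow(search_lines(db, generic = "guest-line%")), 2L)
})

test_that("unknown vocabulary values: ecotype degrades, others must be mapped", {
  db <- make_exportable_db()
  doc <- export_line(db, "donor")
  doc$line$ecotype <- "Ws-4"
  expect_warning(imp <- import_line(db, doc, new_name = "eco-import"),
                 "Ws-4")
  expect_identical(imp$ecotype_label, "(Other)")

  doc2 <- export_line(db, "donor")
  doc2$line$species <- "Zea mays"
  err <- expect_error(import_line(db, doc2, new_name = "sp-import"),
                      class = "seedledger_vocabulary_error")
  expect_match(conditionMessage(err), "Zea mays")
  # mapping the species rescues the import; the Arabidopsis ecotype then
  # degrades to the sentinel with a warning
  expect_warning(
    imp2 <- import_line(db, doc2, new_name = "sp-import",
                        map_unknown = c("Zea mays" = "Oryza sativa")),
    "Col-0"
  )
  expect_identical(imp2$ecotype_label, "(Other)")

  doc3 <- export_line(db, "donor")
  doc3$features[[1]]$mutation_method <- "their-method"
  err <- expect_error(import_line(db, doc3, new_name = "mm-import"),
                      class = "seedledger_vocabulary_error")
  expect_match(conditionMessage(err), "their-method")
})

test_that("batch export yields one batch-free valid document per line", {
  db <- make_exportable_db()
  res <- search_lines(db, show_all = TRUE)
  docs <- export_lines_batch(db, res$line_id)
  expect_length(docs, nrow(res))
  for (d in docs) {
    expect_length(d$seed_batches, 0L)
    expect_true(validate_interchange(d))
  }
  expect_error(export_lines_batch(db, character(0)),
               class = "seedledger_validation_error")
})

test_that("the validator reports the failing location as a JSON pointer", {
  db <- make_exportable_db()
  doc <- export_line(db, "donor")
  expect_true(validate_interchange(doc))

  bad <- doc
  bad$line$name <- NULL
  err <- expect_error(validate_interchange(bad),
                      class = "seedledger_format_error")
  expect_match(conditionMessage(err), "/line/name")

  bad <- doc
  bad$features[[1]]$category <- "SOMETHING"
  err <- expect_error(validate_interchange(bad),
                      class = "seedledger_format_error")
  expect_match(conditionMessage(err), "/features/0/category")

  bad <- doc
  bad$format_version <- "99"
  expect_error(validate_interchange(bad), class = "seedledger_format_error")
})
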