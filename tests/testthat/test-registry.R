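# Line/feature/plant/seed-batch record store.

test_that("line creation enforces exactly the three mandatory fields", {
  db <- make_lab_db()
  err <- expect_error(create_line(db, name = "only-name"),
                      class = "seedledger_validation_error")
  expect_match(conditionMessage(err), "person")
  expect_match(conditionMessage(err), "species")
  expect_false(grepl("name", conditionMessage(err)))

  expect_error(create_line(db, "x", "alice", "Zea mays"),
               class = "seedledger_vocabulary_error")
  expect_error(create_line(db, "x", "dave", "Oryza sativa"),
               class = "seedledger_vocabulary_error")

  # a wild-type line needs nothing else: zero features
  wt <- create_line(db, "WT-Col0", "alice", "Arabidopsis thaliana",
                    ecotype = "Col-0")
  expect_identical(nrow(effective_features(db, wt$id)), 0L)
  expect_false(is_gmo(db, wt$id))
})

test_that("lines persist through a save/open round trip", {
  db <- make_lab_db()
  create_line(db, "WT-Col0", "alice", "Arabidopsis thaliana",
              ecotype = "Col-0", origin = "stock center")
  add_feature(db, "WT-Col0", "TRANSGENESIS", "Pro35S:GUS",
              mutation_method = "T-DNA", sequence = "ATGC")
  path <- withr::local_tempfile(fileext = ".json")
  db_save(db, path)
  db2 <- db_open(path)
  ds <- datasheet(db2, "WT-Col0")
  expect_identical(ds$general_information$person, "alice")
  expect_identical(ds$general_information$ecotype, "Col-0")
  expect_identical(ds$general_information$origin, "stock center")
  expect_identical(ds$genetic_features$designation, "Pro35S:GUS")
})

test_that("feature categories drive the green/blue color classes", {
  db <- make_lab_db()
  ln <- create_line(db, "tg1", "alice", "Arabidopsis thaliana")
  add_feature(db, ln$id, "TRANSGENESIS", "Pro35S:GUS")
  add_feature(db, ln$id, "ENDOGENOUS", "pht1;1-1", mutation_method = "EMS")
  tab <- effective_features(db, ln$id)
  expect_identical(tab$color, c("GREEN", "BLUE"))
  expect_true(is_gmo(db, ln$id))

  # CRISPR event: machinery T-DNA (green) + target locus (blue) on one line
  cr <- create_line(db, "crispr1", "alice", "Arabidopsis thaliana")
  add_feature(db, cr$id, "TRANSGENESIS", "pCas9-sgRNA", mutation_method = "T-DNA")
  add_feature(db, cr$id, "ENDOGENOUS", "tt4-cr1", mutation_method = "CRISPR")
  expect_setequal(effective_features(db, cr$id)$color, c("GREEN", "BLUE"))

  expect_error(add_feature(db, cr$id, "ENDOGENOUS", "x", agro_strain = "GV3101"),
               class = "seedledger_category_error")
  expect_error(add_feature(db, cr$id, "TRANSGENESIS", ""),
               class = "seedledger_validation_error")
  expect_warning(add_feature(db, cr$id, "ENDOGENOUS", "tt4-cr1"),
                 "already owns")
})

test_that("seed-batch system ids are monotone and never reused", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Oryza sativa")
  b1 <- add_seed_batch(db, ln$id, "A")
  b2 <- add_seed_batch(db, ln$id, "A")   # same personal identifier is fine
  b3 <- add_seed_batch(db, ln$id, "B")
  expect_identical(c(b1$system_id, b2$system_id, b3$system_id), c(1L, 2L, 3L))

  delete_seed_batch(db, 2)
  b4 <- add_seed_batch(db, ln$id, "C")
  expect_identical(b4$system_id, 4L)     # 2 is never reallocated

  expect_error(add_seed_batch(db, ln$id, ""),
               class = "seedledger_validation_error")
  expect_error(add_plant(db, ln$id, ""),
               class = "seedledger_validation_error")
})

test_that("randomized create/delete/copy traces respect the id discipline", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Oryza sativa")
  set.seed(421)
  issued <- integer()     # model allocator: every id ever issued, in order
  live <- integer()
  for (i in 1:200) {
    op <- sample(c("create", "delete", "copy"), 1L)
    if (op == "create") {
      b <- add_seed_batch(db, ln$id, paste0("s", i))
      issued <- c(issued, b$system_id)
      live <- c(live, b$system_id)
    } else if (op == "delete" && length(live) > 0L) {
      victim <- live[sample.int(length(live), 1L)]
      delete_seed_batch(db, victim)
      live <- setdiff(live, victim)
    } else if (op == "copy" && length(live) > 0L) {
      b <- copy_record(db, live[sample.int(length(live), 1L)])
      issued <- c(issued, b$system_id)
      live <- c(live, b$system_id)
    }
  }
  expect_false(any(duplicated(issued)))
  expect_true(all(diff(issued) > 0))
  expect_setequal(vapply(db$batches, `[[`, integer(1), "system_id"), live)
})

test_that("copies duplicate fields, stay in their line, and are independent", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Oryza sativa")
  other <- create_line(db, "other", "alice", "Oryza sativa")
  f <- add_feature(db, ln$id, "TRANSGENESIS", "tg")

  b <- add_seed_batch(db, ln$id, "orig", generation_label = "T2",
                      storage_place = "box-9")
  b2 <- copy_record(db, b$system_id)
  expect_gt(b2$system_id, b$system_id)
  expect_identical(b2$personal_identifier, "orig")
  expect_identical(b2$storage_place, "box-9")

  p <- add_plant(db, ln$id, "p1",
                 genotypes = stats::setNames(list("HETEROZYGOUS"), f$id))
  p2 <- copy_record(db, p$id)
  expect_identical(p2$genotypes, p$genotypes)
  set_genotype(db, p2$id, f$id, "HOMOZYGOUS")
  expect_identical(db$plants[[p$id]]$genotypes[[f$id]], "HETEROZYGOUS")

  expect_error(copy_record(db, p$id, line = other$id),
               class = "seedledger_consistency_error")
  expect_error(copy_record(db, "P999"), class = "seedledger_not_found_error")
})

test_that("genotype and segregation maps are restricted to the line's features", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Oryza sativa")
  foreign <- create_line(db, "f", "alice", "Oryza sativa")
  ff <- add_feature(db, foreign$id, "ENDOGENOUS", "xx")
  expect_error(
    add_plant(db, ln$id, "p1",
              genotypes = stats::setNames(list("WT"), ff$id)),
    class = "seedledger_consistency_error"
  )
  expect_error(
    add_seed_batch(db, ln$id, "s1",
                   segregation = stats::setNames(list(list(observed_counts = "3:1")),
                                                 ff$id)),
    class = "seedledger_consistency_error"
  )
})

test_that("insertion sites are per-plant and transgenesis-only", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Arabidopsis thaliana")
  tg <- add_feature(db, ln$id, "TRANSGENESIS", "tdna1")
  en <- add_feature(db, ln$id, "ENDOGENOUS", "ems1")
  p1 <- add_plant(db, ln$id, "T1-1", generation_label = "T1")
  p2 <- add_plant(db, ln$id, "T1-2", generation_label = "T1")

  set_insertion_sites(db, p1$id, tg$id,
                      list(list(location = "Chr1:1234", flanking_sequence = "AAGT")))
  set_insertion_sites(db, p2$id, tg$id, list(list(location = "Chr4:9876")))
  expect_identical(db$plants[[p1$id]]$insertion_sites[[tg$id]][[1]]$location,
                   "Chr1:1234")
  expect_identical(db$plants[[p2$id]]$insertion_sites[[tg$id]][[1]]$location,
                   "Chr4:9876")

  expect_error(set_insertion_sites(db, p1$id, en$id, list(list(location = "x"))),
               class = "seedledger_category_error")

  set_insertion_sites(db, p1$id, tg$id, list())
  expect_null(db$plants[[p1$id]]$insertion_sites[[tg$id]])
})

test_that("locks block edits until unlocked; inherited fields stay read-only", {
  db <- make_lab_db()
  ln <- create_line(db, "parent", "alice", "Arabidopsis thaliana")
  f <- add_feature(db, ln$id, "ENDOGENOUS", "m1")
  child <- mutagenize_line(db, ln$id, list(category = "ENDOGENOUS",
                                           designation = "m2"))

  set_locked(db, ln$id, TRUE)
  expect_error(edit_line(db, ln$id, origin = "x"),
               class = "seedledger_locked_error")
  set_locked(db, ln$id, FALSE)
  expect_silent(edit_line(db, ln$id, origin = "x"))

  # unlocking the child does not unlock what it inherited
  set_locked(db, child$id, FALSE)
  expect_error(edit_feature(db, child$id, f$id, gene = "G"),
               class = "seedledger_immutability_error")

  b <- add_seed_batch(db, ln$id, "s1")
  set_locked(db, b$system_id, TRUE)
  expect_error(edit_seed_batch(db, b$system_id, storage_place = "y"),
               class = "seedledger_locked_error")
})

test_that("lines with descendants or batches cannot be deleted", {
  db <- make_lab_db()
  a <- create_line(db, "a", "alice", "Oryza sativa")
  b <- mutagenize_line(db, a$id, list(category = "ENDOGENOUS", designation = "m"))
  expect_error(delete_line(db, a$id), class = "seedledger_consistency_error")
  add_seed_batch(db, b$id, "s1")
  expect_error(delete_line(db, b$id), class = "seedledger_consistency_error")
  c_ <- create_line(db, "c", "alice", "Oryza sativa")
  expect_silent(delete_line(db, c_$id))
})

test_that("plant and batch tables export as CSV", {
  db <- make_lab_db()
  ln <- create_line(db, "l", "alice", "Oryza sativa")
  add_plant(db, ln$id, "p1", generation_label = "F2", person = "bob")
  add_seed_batch(db, ln$id, "s1", storage_place = "box-3")
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(db, ln$id, "plants", path)
  tab <- utils::read.csv(path)
  expect_identical(tab$personal_identifier, "p1")
  export_table(db, ln$id, "seed_batches", path)
  tab <- utils::read.csv(path)
  expect_identical(tab$system_id, 1L)
  expect_identical(tab$storage_place, "box-3")
})
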