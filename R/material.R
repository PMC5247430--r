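# Physical material: plants and seed batches recorded under a line. Seed
# batches carry a system-allocated id that is strictly increasing over the
# database lifetime and never reallocated, even after deletion — so the id
# printed on a stock tube always resolves unambiguously.

#' Record a plant under a line
#'
#' The personal identifier is the only mandatory field. Genotypes are given
#' per genetic feature of the line (including inherited features); insertion
#' sites can be set per plant for TRANSGENESIS features (see
#' [set_insertion_sites()]).
#'
#' @param db A `seed_db`.
#' @param line Line id or name.
#' @param personal_identifier The user's plant identifier (mandatory).
#' @param generation_label Free-text generation, e.g. `"T1"`, `"F3"`,
#'   `"unknown"`.
#' @param genotypes Named list `feature id -> one of` [genotype_states()].
#' @param phenotype_note Short phenotype description.
#' @param attachments List of [attachment()]s.
#' @param notebook_ref Laboratory-notebook reference.
#' @param person A `PERSON` vocabulary value.
#' @return The new plant record, invisibly.
#' @export
add_plant <- function(db, line, personal_identifier, generation_label = "",
                      genotypes = list(), phenotype_note = "",
                      attachments = list(), notebook_ref = "", person = NULL) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_line(db, line)
  sl_check_identifier(personal_identifier, "plant")
  genotypes <- sl_check_genotypes(db, rec$id, genotypes)
  id <- sl_next_id(db, "plant", "P")
  db$plants[[id]] <- list(
    id = id, line = rec$id, personal_identifier = personal_identifier,
    generation_label = generation_label, genotypes = genotypes,
    insertion_sites = list(), phenotype_note = phenotype_note,
    attachments = attachments, notebook_ref = notebook_ref,
    person = sl_vocab_ref(db, "PERSON", person, "person"), locked = FALSE
  )
  sl_log(db, "add_plant", paste(rec$id, id))
  invisible(db$plants[[id]])
}

sl_check_identifier <- function(x, what) {
  if (is.null(x) || !nzchar(x)) {
    sl_abort("validation_error",
             sprintf("the personal %s identifier is mandatory", what))
  }
  invisible(TRUE)
}

sl_check_genotypes <- function(db, line_id, genotypes) {
  if (length(genotypes) == 0L) return(list())
  eff <- sl_effective_feature_ids(db, line_id)
  bad <- setdiff(names(genotypes), eff)
  if (length(bad) > 0L) {
    sl_abort("consistency_error",
             sprintf("genotype keyed by feature(s) not in this line: %s",
                     paste(bad, collapse = ", ")))
  }
  lapply(genotypes, function(g) match.arg(toupper(g), genotype_states()))
}

#' Record a seed batch under a line
#'
#' The batch receives the next system id (unique, strictly increasing, never
#' reused). Two batches may share a personal identifier; their system ids
#' still distinguish them.
#'
#' @inheritParams add_plant
#' @param mother_plant Optional plant id of the mother plant.
#' @param segregation Named list `feature id -> list(observed_counts, note)`.
#' @param harvest_date Harvest date (text, e.g. `"2026-05-12"`).
#' @param storage_place Where the tube is stored.
#' @param germination_result Free-text germination-assay result.
#' @param germination_attachments,phenotype_attachments Lists of
#'   [attachment()]s.
#' @return The new batch record (with `$system_id`), invisibly.
#' @export
add_seed_batch <- function(db, line, personal_identifier,
                           generation_label = "", mother_plant = NULL,
                           segregation = list(), harvest_date = "",
                           storage_place = "", germination_result = "",
                           germination_attachments = list(),
                           phenotype_note = "", phenotype_attachments = list(),
                           notebook_ref = "", person = NULL) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_line(db, line)
  sl_check_identifier(personal_identifier, "seed batch")
  segregation <- sl_check_segregation(db, rec$id, segregation)
  mother_id <- NULL
  if (!is.null(mother_plant)) {
    mp <- sl_get_plant(db, mother_plant)
    mother_id <- mp$id
  }
  sid <- sl_next_system_id(db)
  db$batches[[as.character(sid)]] <- list(
    system_id = sid, personal_identifier = personal_identifier,
    line = rec$id, generation_label = generation_label,
    mother_plant = mother_id, segregation = segregation,
    harvest_date = harvest_date, storage_place = storage_place,
    germination_result = germination_result,
    germination_attachments = germination_attachments,
    phenotype_note = phenotype_note,
    phenotype_attachments = phenotype_attachments,
    notebook_ref = notebook_ref,
    person = sl_vocab_ref(db, "PERSON", person, "person"), locked = FALSE
  )
  sl_log(db, "add_seed_batch", paste(rec$id, sid))
  invisible(db$batches[[as.character(sid)]])
}

sl_check_segregation <- function(db, line_id, segregation) {
  if (length(segregation) == 0L) return(list())
  eff <- sl_effective_feature_ids(db, line_id)
  bad <- setdiff(names(segregation), eff)
  if (length(bad) > 0L) {
    sl_abort("consistency_error",
             sprintf("segregation keyed by feature(s) not in this line: %s",
                     paste(bad, collapse = ", ")))
  }
  lapply(segregation, function(s) {
    list(observed_counts = s$observed_counts %||% "", note = s$note %||% "")
  })
}

#' Delete a plant or a seed batch
#'
#' A deleted batch's system id is never reallocated.
#'
#' @param db A `seed_db`.
#' @param plant,batch Record id (plant id / batch system id).
#' @return Invisibly `TRUE`.
#' @export
delete_seed_batch <- function(db, batch) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_batch(db, batch)
  db$batches[[as.character(rec$system_id)]] <- NULL
  sl_log(db, "delete_seed_batch", rec$system_id)
  invisible(TRUE)
}

#' @rdname delete_seed_batch
#' @export
delete_plant <- function(db, plant) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_plant(db, plant)
  used <- Filter(function(b) identical(b$mother_plant, rec$id), db$batches)
  if (length(used) > 0L) {
    sl_abort("consistency_error",
             sprintf("plant '%s' is the mother plant of %d seed batch(es)",
                     rec$id, length(used)))
  }
  db$plants[[rec$id]] <- NULL
  sl_log(db, "delete_plant", rec$id)
  invisible(TRUE)
}

#' Duplicate a plant or seed batch record
#'
#' Copies all user fields into a fresh record of the same line (a copy never
#' changes line); a copied batch receives a new system id. The copy is
#' independent: subsequent edits of one record do not affect the other.
#'
#' @param db A `seed_db`.
#' @param record A plant id (`"P<n>"`) or a batch system id.
#' @param line Optional target line; must equal the source record's line
#'   (copying across lines is refused).
#' @return The new record, invisibly.
#' @export
copy_record <- function(db, record, line = NULL) {
  sl_require_role(db, "WRITER")
  id <- as.character(if (is.list(record)) record$id %||% record$system_id else record)
  is_plant <- !is.null(db$plants[[id]])
  is_batch <- !is.null(db$batches[[id]])
  if (!is_plant && !is_batch) {
    sl_abort("not_found_error", sprintf("no plant or seed batch with id '%s'", id))
  }
  src <- if (is_plant) db$plants[[id]] else db$batches[[id]]
  if (!is.null(line)) {
    target <- sl_get_line(db, line)
    if (!identical(target$id, src$line)) {
      sl_abort("consistency_error",
               "a copy stays in its line; copying across lines is refused")
    }
  }
  new <- src
  new$locked <- FALSE
  if (is_plant) {
    new$id <- sl_next_id(db, "plant", "P")
    db$plants[[new$id]] <- new
    sl_log(db, "copy_record", paste(id, "->", new$id))
  } else {
    new$system_id <- sl_next_system_id(db)
    db$batches[[as.character(new$system_id)]] <- new
    sl_log(db, "copy_record", paste(id, "->", new$system_id))
  }
  invisible(new)
}

#' Record per-plant insertion sites of a transgene
#'
#' Independent transformants of one construct are often kept in a single
#' line; the genomic insertion site(s) of the transgene then differ between
#' plants and are stored on each plant individually. Only TRANSGENESIS
#' features can carry insertion sites. An empty `sites` list clears them.
#'
#' @param db A `seed_db`.
#' @param plant Plant id.
#' @param feature Feature id; must be a TRANSGENESIS feature of the plant's
#'   line.
#' @param sites List of `list(location =, flanking_sequence =)`.
#' @return The updated plant, invisibly.
#' @export
set_insertion_sites <- function(db, plant, feature, sites) {
  sl_require_role(db, "WRITER")
  prec <- sl_get_plant(db, plant)
  frec <- sl_get_feature(db, feature)
  sl_check_unlocked(prec, "plant")
  if (!frec$id %in% sl_effective_feature_ids(db, prec$line)) {
    sl_abort("consistency_error",
             sprintf("feature '%s' does not belong to the plant's line", frec$id))
  }
  if (!identical(frec$category, "TRANSGENESIS")) {
    sl_abort("category_error",
             "insertion sites can only be recorded for plants resulting from transgenesis")
  }
  sites <- lapply(sites, function(s) {
    list(location = s$location %||% "", flanking_sequence = s$flanking_sequence %||% "")
  })
  if (length(sites) == 0L) {
    db$plants[[prec$id]]$insertion_sites[[frec$id]] <- NULL
  } else {
    db$plants[[prec$id]]$insertion_sites[[frec$id]] <- sites
  }
  sl_log(db, "set_insertion_sites", paste(prec$id, frec$id, length(sites)))
  invisible(db$plants[[prec$id]])
}

#' Set the genotype of one feature on a plant
#'
#' @param db A `seed_db`.
#' @param plant Plant id.
#' @param feature Feature id (must belong to the plant's line).
#' @param state One of [genotype_states()].
#' @return The updated plant, invisibly.
#' @export
set_genotype <- function(db, plant, feature, state) {
  sl_require_role(db, "WRITER")
  prec <- sl_get_plant(db, plant)
  sl_check_unlocked(prec, "plant")
  g <- prec$genotypes
  g[[as.character(if (is.list(feature)) feature$id else feature)]] <- state
  db$plants[[prec$id]]$genotypes <- sl_check_genotypes(db, prec$line, g)
  sl_log(db, "set_genotype", prec$id)
  invisible(db$plants[[prec$id]])
}

#' Edit user fields of a plant or seed batch
#'
#' Honours the record lock. Fields not given are kept.
#'
#' @param db A `seed_db`.
#' @param plant,batch Record id.
#' @param ... Named replacement values among the record's user fields
#'   (`personal_identifier`, `generation_label`, `phenotype_note`,
#'   `notebook_ref`, `storage_place`, `harvest_date`, `germination_result`).
#' @return The updated record, invisibly.
#' @export
edit_plant <- function(db, plant, ...) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_plant(db, plant)
  sl_check_unlocked(rec, "plant")
  rec <- sl_apply_edits(rec, list(...),
                        c("personal_identifier", "generation_label",
                          "phenotype_note", "notebook_ref"))
  db$plants[[rec$id]] <- rec
  sl_log(db, "edit_plant", rec$id)
  invisible(rec)
}

#' @rdname edit_plant
#' @export
edit_seed_batch <- function(db, batch, ...) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_batch(db, batch)
  sl_check_unlocked(rec, "seed batch")
  rec <- sl_apply_edits(rec, list(...),
                        c("personal_identifier", "generation_label",
                          "phenotype_note", "notebook_ref", "storage_place",
                          "harvest_date", "germination_result"))
  db$batches[[as.character(rec$system_id)]] <- rec
  sl_log(db, "edit_seed_batch", rec$system_id)
  invisible(rec)
}

sl_apply_edits <- function(rec, edits, allowed) {
  bad <- setdiff(names(edits), allowed)
  if (length(bad) > 0L) {
    sl_abort("field_error",
             sprintf("unknown or non-editable field(s): %s; editable fields are: %s",
                     paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  if ("personal_identifier" %in% names(edits)) {
    sl_check_identifier(edits$personal_identifier, "record")
  }
  rec[names(edits)] <- edits
  rec
}

# ---- tables ----------------------------------------------------------------

sl_plant_table <- function(db, line_id) {
  ps <- Filter(function(p) identical(p$line, line_id), db$plants)
  data.frame(
    plant_id = vapply(ps, `[[`, character(1), "id"),
    personal_identifier = vapply(ps, `[[`, character(1), "personal_identifier"),
    generation = vapply(ps, `[[`, character(1), "generation_label"),
    genotypes = vapply(ps, function(p) sl_fmt_map(p$genotypes), character(1)),
    phenotype = vapply(ps, `[[`, character(1), "phenotype_note"),
    person = vapply(ps, function(p) sl_vocab_value(db, p$person) %||% "", character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

sl_batch_table <- function(db, line_id) {
  bs <- Filter(function(b) identical(b$line, line_id), db$batches)
  data.frame(
    system_id = vapply(bs, function(b) as.integer(b$system_id), integer(1)),
    personal_identifier = vapply(bs, `[[`, character(1), "personal_identifier"),
    generation = vapply(bs, `[[`, character(1), "generation_label"),
    mother_plant = vapply(bs, function(b) b$mother_plant %||% "", character(1)),
    harvest_date = vapply(bs, `[[`, character(1), "harvest_date"),
    storage_place = vapply(bs, `[[`, character(1), "storage_place"),
    person = vapply(bs, function(b) sl_vocab_value(db, b$person) %||% "", character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

sl_fmt_map <- function(m) {
  if (length(m) == 0L) return("")
  paste(sprintf("%s=%s", names(m), unlist(m)), collapse = ";")
}

#' Export a line's plant or seed-batch table as CSV
#'
#' One row per record, columns as in [datasheet()].
#'
#' @param db A `seed_db`.
#' @param line Line id or name.
#' @param what `"plants"` or `"seed_batches"`.
#' @param file Output path.
#' @return The data frame written, invisibly.
#' @export
export_table <- function(db, line, what = c("plants", "seed_batches"), file) {
  what <- match.arg(what)
  rec <- sl_get_line(db, line)
  tab <- if (what == "plants") sl_plant_table(db, rec$id) else sl_batch_table(db, rec$id)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}
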