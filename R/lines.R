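# Plant lines: the core record grouping all self/backcross generations that
# share one genetic context (species, ecotype, set of genetic features).
# The datasheet of a line has five sections: general information, genetic
# features, genealogy tree, plants table, seed batches table.

LINE_MANDATORY <- c("name", "person", "species")

#' Create a plant line de novo
#'
#' Exactly three fields are mandatory: the line name, the responsible person
#' and the species. A line created with no genetic features is wild type.
#' The person and species must exist in the controlled vocabulary; the
#' ecotype, when given, must be an ecotype registered for that species.
#'
#' @param db A `seed_db`.
#' @param name Line name.
#' @param person Responsible person (a `PERSON` vocabulary value).
#' @param species Species (a `SPECIES` vocabulary value).
#' @param ecotype Optional ecotype of that species; defaults to `"(Other)"`.
#' @param origin Free-text provenance of the material.
#' @param mta_protected Is the material protected by a Material Transfer
#'   Agreement?
#' @param mta_details Recipient/location/recommendations of the MTA; only
#'   allowed when `mta_protected` is `TRUE`.
#' @return The new line record, invisibly.
#' @examples
#' db <- seed_db()
#' add_vocab_entry(db, "PERSON", "alice")
#' add_vocab_entry(db, "SPECIES", "Arabidopsis thaliana")
#' add_vocab_entry(db, "ECOTYPE", "Col-0", linked_species = "Arabidopsis thaliana")
#' wt <- create_line(db, "WT-Col0", "alice", "Arabidopsis thaliana", ecotype = "Col-0")
#' @export
create_line <- function(db, name = NULL, person = NULL, species = NULL,
                        ecotype = NULL, origin = "", mta_protected = FALSE,
                        mta_details = "") {
  sl_require_role(db, "WRITER")
  given <- c(name = !is.null(name) && nzchar(name),
             person = !is.null(person) && nzchar(person),
             species = !is.null(species) && nzchar(species))
  if (!all(given)) {
    missing <- names(given)[!given]
    sl_abort("validation_error",
             sprintf("missing mandatory field%s: %s",
                     if (length(missing) == 1L) "" else "s",
                     paste(missing, collapse = ", ")),
             missing_fields = missing)
  }
  person_id <- sl_vocab_ref(db, "PERSON", person, "person")
  species_id <- sl_vocab_ref(db, "SPECIES", species, "species")
  if (is.null(ecotype)) ecotype <- OTHER_ECOTYPE
  eco <- sl_ecotype_find(db, ecotype, species_id)
  if (is.null(eco)) {
    sl_abort("vocabulary_error",
             sprintf("ecotype '%s' is not registered for species '%s'",
                     ecotype, species))
  }
  sl_new_line(db, name = name, person = person_id, species = species_id,
              ecotype_label = eco$value, origin = origin,
              creation_mode = "NEW", parents = list(),
              mta = sl_mta(mta_protected, mta_details))
}

sl_mta <- function(protected, details = "") {
  protected <- isTRUE(protected)
  if (!protected && nzchar(details)) {
    sl_abort("validation_error",
             "MTA details may only be recorded when the line is MTA-protected")
  }
  list(protected = protected, details = details)
}

# shared constructor for all four creation modes
sl_new_line <- function(db, name, person, species, ecotype_label, origin,
                        creation_mode, parents, mta,
                        files_from_source = list()) {
  id <- sl_next_id(db, "line", "L")
  db$lines[[id]] <- list(
    id = id, name = name, person = person, species = species,
    ecotype_label = ecotype_label, origin = origin,
    files_from_source = files_from_source,
    mta = mta, creation_mode = creation_mode, parents = parents,
    features = character(), locked = FALSE
  )
  sl_log(db, "create_line", paste(id, name, creation_mode))
  invisible(db$lines[[id]])
}

#' Edit general-information fields of a line
#'
#' Permitted for writers while the line is unlocked. Parent links, creation
#' mode and the feature list cannot be edited this way.
#'
#' @param db A `seed_db`.
#' @param line Line id or name.
#' @param name,person,ecotype,origin New values (omit to keep).
#' @param mta_protected,mta_details New MTA status/details (omit to keep).
#' @return The updated record, invisibly.
#' @export
edit_line <- function(db, line, name = NULL, person = NULL, ecotype = NULL,
                      origin = NULL, mta_protected = NULL, mta_details = NULL) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_line(db, line)
  sl_check_unlocked(rec, "line")
  if (!is.null(name)) {
    if (!nzchar(name)) sl_abort("validation_error", "line name must be non-empty")
    rec$name <- name
  }
  if (!is.null(person)) rec$person <- sl_vocab_ref(db, "PERSON", person, "person")
  if (!is.null(ecotype)) {
    eco <- sl_ecotype_find(db, ecotype, rec$species)
    if (is.null(eco) && rec$creation_mode != "CROSS") {
      sl_abort("vocabulary_error",
               sprintf("ecotype '%s' is not registered for this species", ecotype))
    }
    rec$ecotype_label <- if (is.null(eco)) ecotype else eco$value
  }
  if (!is.null(origin)) rec$origin <- origin
  if (!is.null(mta_protected) || !is.null(mta_details)) {
    prot <- if (is.null(mta_protected)) rec$mta$protected else isTRUE(mta_protected)
    det <- if (is.null(mta_details)) rec$mta$details else mta_details
    if (!prot) det <- ""
    rec$mta <- sl_mta(prot, det)
  }
  db$lines[[rec$id]] <- rec
  sl_log(db, "edit_line", rec$id)
  invisible(rec)
}

#' Mark a line as MTA-protected
#'
#' @inheritParams edit_line
#' @param protected Logical MTA flag.
#' @param details Free-text recipient/location/recommendations.
#' @return The updated record, invisibly.
#' @export
set_mta <- function(db, line, protected, details = "") {
  edit_line(db, line, mta_protected = protected,
            mta_details = if (isTRUE(protected)) details else "")
}

sl_check_unlocked <- function(rec, what) {
  if (isTRUE(rec$locked)) {
    sl_abort("locked_error",
             sprintf("%s '%s' is locked; unlock it before editing",
                     what, rec$id %||% rec$system_id))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lock or unlock a record against edits
#'
#' Works on lines (`"L<n>"`), genetic features (`"F<n>"`), plants (`"P<n>"`)
#' and seed batches (system id). Locking protects a finished record from
#' accidental edits; fields inherited from a parental line are read-only
#' regardless of lock state.
#'
#' @param db A `seed_db`.
#' @param record A record id.
#' @param locked Logical.
#' @return Invisibly `TRUE`.
#' @export
set_locked <- function(db, record, locked) {
  sl_require_role(db, "WRITER")
  id <- as.character(if (is.list(record)) record$id %||% record$system_id else record)
  for (tab in c("lines", "features", "plants", "batches")) {
    if (!is.null(db[[tab]][[id]])) {
      db[[tab]][[id]]$locked <- isTRUE(locked)
      sl_log(db, "set_locked", paste(id, locked))
      return(invisible(TRUE))
    }
  }
  sl_abort("not_found_error", sprintf("no record with id '%s'", id))
}

#' Delete a plant line
#'
#' Refused while the line has descendant lines or seed batches, protecting
#' pedigree integrity and the no-reuse guarantee of batch ids.
#'
#' @inheritParams edit_line
#' @return Invisibly `TRUE`.
#' @export
delete_line <- function(db, line) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_line(db, line)
  kids <- sl_children(db, rec$id)
  if (length(kids) > 0L) {
    sl_abort("consistency_error",
             sprintf("line '%s' has %d descendant line(s) and cannot be deleted",
                     rec$name, length(kids)))
  }
  nb <- sum(vapply(db$batches, function(b) identical(b$line, rec$id), logical(1)))
  if (nb > 0L) {
    sl_abort("consistency_error",
             sprintf("line '%s' has %d seed batch(es) and cannot be deleted",
                     rec$name, nb))
  }
  for (fid in rec$features) db$features[[fid]] <- NULL
  keep <- !vapply(db$plants, function(p) identical(p$line, rec$id), logical(1))
  db$plants <- db$plants[keep]
  db$lines[[rec$id]] <- NULL
  sl_log(db, "delete_line", rec$id)
  invisible(TRUE)
}

#' Assemble the five-section datasheet of a line
#'
#' @inheritParams edit_line
#' @return A list with components `general_information`, `genetic_features`
#'   (the effective feature table, see [effective_features()]),
#'   `genealogy_tree` (an igraph object), `plants` and `seed_batches`
#'   (data frames).
#' @export
datasheet <- function(db, line) {
  rec <- sl_get_line(db, line)
  list(
    general_information = list(
      name = rec$name,
      person = sl_vocab_value(db, rec$person),
      species = sl_vocab_value(db, rec$species),
      ecotype = rec$ecotype_label,
      origin = rec$origin,
      creation_mode = rec$creation_mode,
      mta = rec$mta,
      files_from_source = vapply(rec$files_from_source,
                                 function(a) a$filename, character(1))
    ),
    genetic_features = effective_features(db, rec$id),
    genealogy_tree = ancestry_tree(db, rec$id),
    plants = sl_plant_table(db, rec$id),
    seed_batches = sl_batch_table(db, rec$id)
  )
}
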