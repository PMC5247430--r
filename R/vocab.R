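# Controlled vocabularies and user accounts. Seven vocabulary categories
# parameterize every scroll-down choice in the registry; entries are
# referenced by stable internal ids so renaming an entry updates every record
# that uses it. Uniqueness of (category, value) is case-insensitive.

#' Create a user account
#'
#' Accounts carry one of three rights levels: `READER` (read only), `WRITER`
#' (read and write records) and `ADMINISTRATOR` (additionally edits
#' vocabularies and accounts). The lattice is total: everything a READER may
#' do a WRITER may do, and everything a WRITER may do an ADMINISTRATOR may do.
#'
#' @param db A `seed_db`.
#' @param login Unique login.
#' @param role One of `"READER"`, `"WRITER"`, `"ADMINISTRATOR"`.
#' @param password Optional password (salted hash stored).
#' @return The account record, invisibly.
#' @export
create_user <- function(db, login, role, password = NULL) {
  sl_require_role(db, "ADMINISTRATOR")
  role <- match.arg(toupper(role), ROLES)
  if (!nzchar(login)) sl_abort("validation_error", "login must be non-empty")
  if (!is.null(db$users[[login]])) {
    sl_abort("conflict_error", sprintf("login '%s' is already taken", login))
  }
  salt <- paste(sample(c(letters, 0:9), 12, replace = TRUE), collapse = "")
  db$users[[login]] <- list(login = login, role = role, salt = salt,
                            password_hash = sl_hash(salt, password))
  sl_log(db, "create_user", paste(login, role))
  invisible(db$users[[login]])
}

sl_vocab_find <- function(db, category, value) {
  for (v in db$vocab) {
    if (identical(v$category, category) &&
        tolower(v$value) == tolower(value)) {
      return(v)
    }
  }
  NULL
}

sl_vocab_get <- function(db, category, value) {
  v <- sl_vocab_find(db, category, value)
  if (is.null(v)) {
    sl_abort("not_found_error",
             sprintf("no %s vocabulary entry '%s'", category, value))
  }
  v
}

#' Add a controlled-vocabulary entry
#'
#' Administrators populate the scroll-down menus of the user mode. Ecotypes
#' are species-specific, so the species must already be registered
#' (`linked_species`); mutation methods must declare which feature category
#' (`TRANSGENESIS` or `ENDOGENOUS`) they produce. Registering a species also
#' seeds the reserved sentinel ecotype `"(Other)"` for it.
#'
#' @param db A `seed_db`.
#' @param category One of [vocab_categories()].
#' @param value Entry text; `(category, value)` is unique, case-insensitively.
#' @param linked_species For `ECOTYPE` entries, the species the ecotype
#'   belongs to (an existing `SPECIES` value).
#' @param feature_category For `MUTATION_METHOD` entries, the feature category
#'   the method produces.
#' @return The new entry, invisibly.
#' @export
add_vocab_entry <- function(db, category, value, linked_species = NULL,
                            feature_category = NULL) {
  sl_require_role(db, "ADMINISTRATOR")
  category <- match.arg(toupper(category), vocab_categories())
  if (!nzchar(value)) sl_abort("validation_error", "vocabulary value must be non-empty")
  if (!is.null(sl_vocab_find(db, category, value))) {
    sl_abort("conflict_error",
             sprintf("%s entry '%s' already exists", category, value))
  }
  species_id <- NULL
  if (category == "ECOTYPE") {
    if (is.null(linked_species)) {
      sl_abort("dependency_error", "an ecotype must name its species")
    }
    sp <- sl_vocab_find(db, "SPECIES", linked_species)
    if (is.null(sp)) {
      sl_abort("dependency_error",
               sprintf(paste("species '%s' is not registered; new species must",
                             "be recorded before registering ecotypes"),
                       linked_species))
    }
    species_id <- sp$id
  }
  if (category == "MUTATION_METHOD") {
    if (is.null(feature_category)) {
      sl_abort("dependency_error",
               "a mutation method must declare its genetic-feature category")
    }
    feature_category <- match.arg(toupper(feature_category), feature_categories())
  } else {
    feature_category <- NULL
  }
  id <- sl_next_id(db, "vocab", "V")
  db$vocab[[id]] <- list(id = id, category = category, value = value,
                         active = TRUE, linked_species = species_id,
                         feature_category = feature_category)
  sl_log(db, "add_vocab_entry", paste(category, value))
  if (category == "SPECIES" &&
      is.null(sl_ecotype_find(db, OTHER_ECOTYPE, id))) {
    eid <- sl_next_id(db, "vocab", "V")
    db$vocab[[eid]] <- list(id = eid, category = "ECOTYPE",
                            value = OTHER_ECOTYPE, active = TRUE,
                            linked_species = id, feature_category = NULL)
  }
  invisible(db$vocab[[id]])
}

# ecotype lookup scoped to one species id
sl_ecotype_find <- function(db, value, species_id) {
  for (v in db$vocab) {
    if (identical(v$category, "ECOTYPE") &&
        tolower(v$value) == tolower(value) &&
        identical(v$linked_species, species_id)) {
      return(v)
    }
  }
  NULL
}

#' List the menu options of a vocabulary category
#'
#' Returns the values a user sees in the corresponding scroll-down menu:
#' active entries only (deactivated persons are hidden), and for ecotypes,
#' only those linked to the given species.
#'
#' @param db A `seed_db`.
#' @param category One of [vocab_categories()].
#' @param species For `ECOTYPE`, restrict to this species' ecotypes.
#' @return Character vector of menu values.
#' @export
vocab_menu <- function(db, category, species = NULL) {
  category <- match.arg(toupper(category), vocab_categories())
  species_id <- if (!is.null(species)) sl_vocab_get(db, "SPECIES", species)$id
  vals <- character()
  for (v in db$vocab) {
    if (!identical(v$category, category)) next
    if (!isTRUE(v$active)) next
    if (!is.null(species_id) && !identical(v$linked_species, species_id)) next
    vals <- c(vals, v$value)
  }
  vals
}

#' Count the records referencing a vocabulary entry
#'
#' Scans lines, genetic features, plants and seed batches and counts each
#' record once if it references the entry (person fields, species, ecotype
#' label, mutation method, method reference, strain, resistance). Deletion of
#' an entry is only permitted while this count is zero.
#'
#' @param db A `seed_db`.
#' @param category,value Identify the entry.
#' @return Non-negative integer count.
#' @export
usage_count <- function(db, category, value) {
  v <- sl_vocab_get(db, match.arg(toupper(category), vocab_categories()), value)
  n <- 0L
  for (l in db$lines) {
    hit <- identical(l$person, v$id) || identical(l$species, v$id)
    if (!hit && v$category == "ECOTYPE" && !is.null(l$ecotype_label) &&
        nzchar(l$ecotype_label) &&
        tolower(l$ecotype_label) == tolower(v$value) &&
        identical(l$species, v$linked_species)) {
      hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  for (f in db$features) {
    hit <- identical(f$mutation_method, v$id) ||
      identical(f$method_reference, v$id) ||
      identical(f$agro_strain, v$id) ||
      identical(f$selectable_resistance, v$id)
    if (hit) n <- n + 1L
  }
  for (p in db$plants) if (identical(p$person, v$id)) n <- n + 1L
  for (b in db$batches) if (identical(b$person, v$id)) n <- n + 1L
  n
}

#' Delete an unused vocabulary entry
#'
#' Refused while any record references the entry (the error names the
#' referencing record count), and always refused for the reserved `"(Other)"`
#' ecotype sentinel.
#'
#' @inheritParams usage_count
#' @return Invisibly `TRUE`.
#' @export
delete_vocab_entry <- function(db, category, value) {
  sl_require_role(db, "ADMINISTRATOR")
  category <- match.arg(toupper(category), vocab_categories())
  v <- sl_vocab_get(db, category, value)
  if (category == "ECOTYPE" && identical(v$value, OTHER_ECOTYPE)) {
    sl_abort("reserved_error",
             "the '(Other)' ecotype is reserved and cannot be deleted")
  }
  n <- usage_count(db, category, value)
  if (n > 0L) {
    sl_abort("in_use_error",
             sprintf("%s entry '%s' is referenced by %d record%s and cannot be deleted",
                     category, value, n, if (n == 1L) "" else "s"),
             n_referencing = n)
  }
  if (category == "SPECIES") {
    ecos <- Filter(function(e) identical(e$category, "ECOTYPE") &&
                     identical(e$linked_species, v$id), db$vocab)
    named <- Filter(function(e) !identical(e$value, OTHER_ECOTYPE), ecos)
    if (length(named) > 0L) {
      sl_abort("dependency_error",
               sprintf("species '%s' still has %d registered ecotype(s); delete them first",
                       value, length(named)))
    }
    for (e in ecos) db$vocab[[e$id]] <- NULL  # cascade the sentinel
  }
  db$vocab[[v$id]] <- NULL
  sl_log(db, "delete_vocab_entry", paste(category, value))
  invisible(TRUE)
}

#' Rename a vocabulary entry
#'
#' Records reference entries by internal id, so every record using the entry
#' displays the new value immediately.
#'
#' @inheritParams usage_count
#' @param new_value Replacement text.
#' @return The updated entry, invisibly.
#' @export
rename_vocab_entry <- function(db, category, value, new_value) {
  sl_require_role(db, "ADMINISTRATOR")
  category <- match.arg(toupper(category), vocab_categories())
  v <- sl_vocab_get(db, category, value)
  clash <- sl_vocab_find(db, category, new_value)
  if (!is.null(clash) && !identical(clash$id, v$id)) {
    sl_abort("conflict_error",
             sprintf("%s entry '%s' already exists", category, new_value))
  }
  db$vocab[[v$id]]$value <- new_value
  sl_log(db, "rename_vocab_entry", paste(category, value, "->", new_value))
  invisible(db$vocab[[v$id]])
}

#' Deactivate or reactivate a person
#'
#' Deactivated persons disappear from the menus offered for new entries, but
#' records that already reference them keep displaying the name.
#'
#' @param db A `seed_db`.
#' @param value The `PERSON` entry value.
#' @param active `FALSE` hides the person from menus, `TRUE` restores it.
#' @return The updated entry, invisibly.
#' @export
set_person_active <- function(db, value, active) {
  sl_require_role(db, "ADMINISTRATOR")
  v <- sl_vocab_get(db, "PERSON", value)
  if (!identical(v$category, "PERSON")) {
    sl_abort("category_error", "only PERSON entries can be (de)activated")
  }
  db$vocab[[v$id]]$active <- isTRUE(active)
  sl_log(db, "set_person_active", paste(value, active))
  invisible(db$vocab[[v$id]])
}

# resolve a vocabulary value to its id, with a vocabulary error naming the
# category when absent
sl_vocab_ref <- function(db, category, value, field) {
  if (is.null(value)) return(NULL)
  v <- sl_vocab_find(db, category, value)
  if (is.null(v)) {
    sl_abort("vocabulary_error",
             sprintf("%s '%s' is not in the %s vocabulary; an administrator must add it",
                     field, value, category))
  }
  v$id
}

sl_vocab_value <- function(db, id) {
  if (is.null(id)) return(NULL)
  db$vocab[[id]]$value
}
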