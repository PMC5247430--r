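# Environment-backed registry. A seed_db is a mutable handle (like a database
# connection): record tables live in an environment and write operations
# modify it in place. db_save()/db_open() persist the whole registry as a
# single JSON file with attachments base64-embedded.

ROLES <- c("READER", "WRITER", "ADMINISTRATOR")

#' Structural constants of the registry
#'
#' The datasheet of a plant line has five sections (general information,
#' genetic features, genealogy tree, plants table, seed batches table); the
#' administrative mode has eight tabs (user accounts plus seven controlled
#' vocabularies); genetic features fall in exactly two categories; lines are
#' created through exactly four modes.
#'
#' @return A character vector naming the sections/tabs/categories/modes.
#' @export
datasheet_sections <- function() {
  c("general_information", "genetic_features", "genealogy_tree",
    "plants", "seed_batches")
}

#' @rdname datasheet_sections
#' @export
admin_tabs <- function() {
  c("USERS", vocab_categories())
}

#' @rdname datasheet_sections
#' @export
vocab_categories <- function() {
  c("PERSON", "SPECIES", "ECOTYPE", "MUTATION_METHOD",
    "METHOD_REFERENCE", "STRAIN", "RESISTANCE")
}

#' @rdname datasheet_sections
#' @export
feature_categories <- function() {
  c("TRANSGENESIS", "ENDOGENOUS")
}

#' @rdname datasheet_sections
#' @export
creation_modes <- function() {
  c("NEW", "CROSS", "MUTAG", "IMPORT")
}

#' @rdname datasheet_sections
#' @export
genotype_states <- function() {
  c("WT", "HETEROZYGOUS", "HOMOZYGOUS", "UNKNOWN")
}

OTHER_ECOTYPE <- "(Other)"

#' Create a new registry
#'
#' Initialises an empty registry with an administrator account (logged in),
#' and the pre-seeded vocabulary defaults: common mutation methods of both
#' feature categories, a few selection resistances and Agrobacterium strains.
#' Whenever a species is registered, the sentinel ecotype `"(Other)"` is
#' seeded for it automatically; it is reserved and cannot be deleted.
#'
#' @param admin_login Login of the administrator account created with the
#'   database.
#' @param admin_password Optional password for that account.
#' @param seed_defaults Seed the default vocabulary entries (default `TRUE`).
#' @return A `seed_db` handle.
#' @examples
#' db <- seed_db()
#' vocab_menu(db, "MUTATION_METHOD")
#' @export
seed_db <- function(admin_login = "admin", admin_password = NULL,
                    seed_defaults = TRUE) {
  db <- new.env(parent = emptyenv())
  db$users <- list()
  db$vocab <- list()
  db$lines <- list()
  db$features <- list()
  db$plants <- list()
  db$batches <- list()
  db$counters <- list(vocab = 0L, line = 0L, feature = 0L, plant = 0L,
                      batch = 0L)
  db$current_user <- NULL
  db$log <- list()
  class(db) <- "seed_db"

  # bootstrap admin without permission checks
  salt <- paste(sample(c(letters, 0:9), 12, replace = TRUE), collapse = "")
  db$users[[admin_login]] <- list(
    login = admin_login, role = "ADMINISTRATOR",
    salt = salt,
    password_hash = sl_hash(salt, admin_password)
  )
  db$current_user <- admin_login

  if (seed_defaults) sl_seed_defaults(db)
  db
}

sl_hash <- function(salt, password) {
  if (is.null(password)) return(NA_character_)
  rlang::hash(paste0(salt, ":", password))
}

sl_seed_defaults <- function(db) {
  methods <- list(
    c("T-DNA", "TRANSGENESIS"),
    c("Transposon", "TRANSGENESIS"),
    c("EMS", "ENDOGENOUS"),
    c("CRISPR", "ENDOGENOUS"),
    c("Gamma irradiation", "ENDOGENOUS"),
    c("Natural variant", "ENDOGENOUS")
  )
  for (m in methods) {
    add_vocab_entry(db, "MUTATION_METHOD", m[[1]], feature_category = m[[2]])
  }
  for (r in c("Kanamycin", "Hygromycin", "BASTA")) {
    add_vocab_entry(db, "RESISTANCE", r)
  }
  for (s in c("GV3101", "C58C1")) add_vocab_entry(db, "STRAIN", s)
  invisible(db)
}

#' @export
print.seed_db <- function(x, ...) {
  cat("<seed_db>", length(x$lines), "lines,", length(x$features),
      "features,", length(x$plants), "plants,", length(x$batches),
      "seed batches\n")
  cat("  user:", if (is.null(x$current_user)) "<none>" else x$current_user,
      "| vocabulary entries:", length(x$vocab), "\n")
  invisible(x)
}

# ---- sessions and roles ----------------------------------------------------

#' Log in / out of a registry
#'
#' Authentication is a thin gate for a single-lab trust model: a password is
#' checked only when the account has one.
#'
#' @param db A `seed_db`.
#' @param login Account login.
#' @param password Password, if the account has one.
#' @return The db handle, invisibly.
#' @export
db_login <- function(db, login, password = NULL) {
  u <- db$users[[login]]
  if (is.null(u)) sl_abort("not_found_error", sprintf("unknown login '%s'", login))
  ph <- u$password_hash
  if (is.null(ph)) ph <- NA_character_   # JSON round trip turns NA into null
  if (!is.na(ph) && !identical(sl_hash(u$salt, password), ph)) {
    sl_abort("authorization_error", sprintf("wrong password for '%s'", login))
  }
  db$current_user <- login
  invisible(db)
}

#' @rdname db_login
#' @export
db_logout <- function(db) {
  db$current_user <- NULL
  invisible(db)
}

sl_role <- function(db) {
  if (is.null(db$current_user)) return(NULL)
  db$users[[db$current_user]]$role
}

# role lattice: ADMINISTRATOR > WRITER > READER
sl_require_role <- function(db, least) {
  role <- sl_role(db)
  if (is.null(role)) {
    sl_abort("authorization_error", "no user logged in")
  }
  if (match(role, ROLES) < match(least, ROLES)) {
    sl_abort("authorization_error",
             sprintf("operation requires %s rights; '%s' has %s rights",
                     least, db$current_user, role))
  }
  invisible(TRUE)
}

sl_log <- function(db, op, detail = "") {
  db$log[[length(db$log) + 1L]] <- list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    login = if (is.null(db$current_user)) NA_character_ else db$current_user,
    op = op, detail = detail
  )
  invisible(db)
}

# ---- id allocation ---------------------------------------------------------

sl_next_id <- function(db, kind, prefix) {
  db$counters[[kind]] <- db$counters[[kind]] + 1L
  paste0(prefix, db$counters[[kind]])
}

# seed-batch system ids are bare positive integers; the counter is never
# rewound, so deleted ids are never reallocated
sl_next_system_id <- function(db) {
  db$counters$batch <- db$counters$batch + 1L
  db$counters$batch
}

# ---- record resolution -----------------------------------------------------

sl_get_line <- function(db, line) {
  if (is.list(line) && !is.null(line$id)) line <- line$id
  rec <- db$lines[[as.character(line)]]
  if (!is.null(rec)) return(rec)
  # fall back to name lookup
  hits <- Filter(function(l) identical(l$name, line), db$lines)
  if (length(hits) == 1L) return(hits[[1L]])
  if (length(hits) > 1L) {
    sl_abort("validation_error",
             sprintf("line name '%s' is ambiguous (%d lines); use the id",
                     line, length(hits)))
  }
  sl_abort("not_found_error", sprintf("no such line: '%s'", line))
}

sl_get_feature <- function(db, feature) {
  if (is.list(feature) && !is.null(feature$id)) feature <- feature$id
  rec <- db$features[[as.character(feature)]]
  if (is.null(rec)) {
    sl_abort("not_found_error", sprintf("no such genetic feature: '%s'", feature))
  }
  rec
}

sl_get_plant <- function(db, plant) {
  if (is.list(plant) && !is.null(plant$id)) plant <- plant$id
  rec <- db$plants[[as.character(plant)]]
  if (is.null(rec)) sl_abort("not_found_error", sprintf("no such plant: '%s'", plant))
  rec
}

sl_get_batch <- function(db, batch) {
  if (is.list(batch) && !is.null(batch$system_id)) batch <- batch$system_id
  rec <- db$batches[[as.character(batch)]]
  if (is.null(rec)) {
    sl_abort("not_found_error", sprintf("no such seed batch: '%s'", batch))
  }
  rec
}

# ---- attachments -----------------------------------------------------------

#' Build an attachment
#'
#' Attachments are stored as embedded bytes with a filename and media type so
#' that exports are self-contained and round-trip byte-exactly.
#'
#' @param filename File name shown to users.
#' @param content A raw vector, or a character scalar (encoded as UTF-8).
#' @param media_type MIME type of the content.
#' @return An `sl_attachment` list.
#' @export
attachment <- function(filename, content, media_type = "application/octet-stream") {
  if (is.character(content)) content <- charToRaw(enc2utf8(paste(content, collapse = "\n")))
  if (!is.raw(content)) {
    sl_abort("validation_error", "attachment content must be raw bytes or text")
  }
  structure(list(filename = filename, media_type = media_type,
                 content = content),
            class = "sl_attachment")
}

# ---- persistence -----------------------------------------------------------

#' Save / open a registry as a single JSON file
#'
#' The whole registry — vocabulary, accounts, lines, features, plants, seed
#' batches, counters and the write log — is serialized to one JSON document.
#' Attachment bytes are base64-encoded. `db_open()` restores an equivalent
#' handle; the session user is not persisted.
#'
#' @param db A `seed_db`.
#' @param path Path of the JSON database file.
#' @return `db_save()` returns the path invisibly; `db_open()` a `seed_db`.
#' @export
db_save <- function(db, path) {
  ser_att <- function(a) list(filename = a$filename, media_type = a$media_type,
                              content = jsonlite::base64_enc(a$content))
  ser_atts <- function(as) lapply(as, ser_att)
  ser_rec <- function(r) {
    for (f in c("files_from_source", "attachments", "protocol_attachments",
                "germination_attachments", "phenotype_attachments")) {
      if (!is.null(r[[f]])) r[[f]] <- ser_atts(r[[f]])
    }
    r
  }
  doc <- list(
    seedledger_db_version = "1",
    users = db$users,
    vocab = db$vocab,
    lines = lapply(db$lines, ser_rec),
    features = lapply(db$features, ser_rec),
    plants = lapply(db$plants, ser_rec),
    batches = lapply(db$batches, ser_rec),
    counters = db$counters,
    log = db$log
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname db_save
#' @export
db_open <- function(path) {
  if (!file.exists(path)) {
    sl_abort("not_found_error", sprintf("no database file at '%s'", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$seedledger_db_version, "1")) {
    sl_abort("format_error", "not a seedledger database file (missing version)")
  }
  de_att <- function(a) attachment(a$filename, jsonlite::base64_dec(a$content),
                                   a$media_type)
  de_rec <- function(r) {
    for (f in c("files_from_source", "attachments", "protocol_attachments",
                "germination_attachments", "phenotype_attachments")) {
      if (!is.null(r[[f]])) r[[f]] <- lapply(r[[f]], de_att)
    }
    r
  }
  de_line <- function(r) {
    r <- de_rec(r)
    r$features <- as.character(unlist(r$features))   # JSON arrays come back as lists
    r$parents <- lapply(r$parents, function(p) {
      p$batch <- if (!is.null(p$batch)) as.integer(p$batch)
      p
    })
    r
  }
  de_batch <- function(r) {
    r <- de_rec(r)
    r$system_id <- as.integer(r$system_id)
    r
  }
  db <- new.env(parent = emptyenv())
  db$users <- doc$users
  db$vocab <- doc$vocab
  db$lines <- lapply(doc$lines, de_line)
  db$features <- lapply(doc$features, de_rec)
  db$plants <- lapply(doc$plants, de_rec)
  db$batches <- lapply(doc$batches, de_batch)
  db$counters <- lapply(doc$counters, as.integer)
  db$log <- doc$log
  db$current_user <- NULL
  class(db) <- "seed_db"
  db
}
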