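# JSON interchange: one exported plant line (optionally with seed batches,
# their mother plants, and all attachments) in a single self-contained file.
# The exporter works by ALLOWLIST: only the fields below are emitted, so the
# sensitive set — person names, notebook references, storage places, MTA
# details — can never leak. The MTA protected flag itself is preserved.
# Inherited features are flattened to copies with their origin-line name kept
# as provenance text, because parental links are severed on import.

INTERCHANGE_VERSION <- "1"

sl_ser_attachment <- function(a) {
  list(filename = a$filename, media_type = a$media_type,
       content = jsonlite::base64_enc(a$content))
}

sl_de_attachment <- function(a) {
  attachment(a$filename, jsonlite::base64_dec(a$content), a$media_type)
}

#' Export one plant line as an interchange document
#'
#' Assembles the line's general information (minus redacted fields), its
#' effective genetic features (inherited ones flattened to copies with
#' `"from <line>"` provenance text), the requested seed batches, any plant
#' referenced as mother by an exported batch, all attachments
#' (base64-embedded), and the genealogy rendered as embedded DOT text. The
#' MTA protected flag is preserved; the MTA details field is left empty.
#'
#' @param db A `seed_db`.
#' @param line Line id or name.
#' @param batches System ids of seed batches to include; each must belong to
#'   the line.
#' @return An `interchange_document` list; write it with
#'   [write_interchange()].
#' @export
export_line <- function(db, line, batches = NULL) {
  rec <- sl_get_line(db, line)
  batch_recs <- lapply(batches, function(b) {
    br <- sl_get_batch(db, b)
    if (!identical(br$line, rec$id)) {
      sl_abort("consistency_error",
               sprintf("seed batch %d does not belong to line '%s'",
                       br$system_id, rec$name))
    }
    br
  })

  eff <- sl_effective_feature_ids(db, rec$id)
  feat_index <- stats::setNames(seq_along(eff), eff)
  features <- lapply(eff, function(fid) {
    f <- db$features[[fid]]
    inherited <- !identical(f$origin_line, rec$id)
    list(
      designation = f$designation,
      category = f$category,
      provenance = if (inherited) {
        paste0("from ", db$lines[[f$origin_line]]$name)
      } else if (nzchar(f$provenance %||% "")) f$provenance else "",
      gene = f$gene %||% "",
      mutation_method = sl_vocab_value(db, f$mutation_method),
      method_reference = sl_vocab_value(db, f$method_reference),
      sequence = f$sequence %||% "",
      selectable_resistance = sl_vocab_value(db, f$selectable_resistance),
      agro_strain = sl_vocab_value(db, f$agro_strain),
      genotyping_protocol = f$genotyping_protocol %||% "",
      protocol_attachments = lapply(f$protocol_attachments, sl_ser_attachment)
    )
  })

  # plants referenced as mother by an exported batch come along
  mother_ids <- unique(unlist(lapply(batch_recs, function(b) b$mother_plant)))
  mother_index <- stats::setNames(seq_along(mother_ids), mother_ids)
  rekey <- function(m) {
    if (length(m) == 0L) return(list())
    stats::setNames(m, as.character(feat_index[names(m)]))
  }
  mother_plants <- lapply(mother_ids, function(pid) {
    p <- db$plants[[pid]]
    list(
      personal_identifier = p$personal_identifier,
      generation_label = p$generation_label,
      genotypes = rekey(p$genotypes),
      insertion_sites = rekey(p$insertion_sites),
      phenotype_note = p$phenotype_note,
      attachments = lapply(p$attachments, sl_ser_attachment)
    )
  })

  seed_batches <- lapply(batch_recs, function(b) {
    list(
      personal_identifier = b$personal_identifier,
      generation_label = b$generation_label,
      mother_plant = if (!is.null(b$mother_plant)) {
        as.integer(mother_index[[b$mother_plant]])
      },
      segregation = rekey(b$segregation),
      harvest_date = b$harvest_date,
      germination_result = b$germination_result,
      germination_attachments = lapply(b$germination_attachments,
                                       sl_ser_attachment),
      phenotype_note = b$phenotype_note,
      phenotype_attachments = lapply(b$phenotype_attachments, sl_ser_attachment)
    )
  })

  doc <- list(
    format_version = INTERCHANGE_VERSION,
    line = list(
      name = rec$name,
      species = sl_vocab_value(db, rec$species),
      ecotype = rec$ecotype_label,
      origin = rec$origin,
      mta = list(protected = isTRUE(rec$mta$protected), details = ""),
      files_from_source = lapply(rec$files_from_source, sl_ser_attachment)
    ),
    features = features,
    seed_batches = seed_batches,
    mother_plants = mother_plants,
    tree_image = sl_ser_attachment(
      attachment("genealogy.gv", sl_tree_dot(db, rec$id), "text/vnd.graphviz")
    )
  )
  class(doc) <- "interchange_document"
  doc
}

#' Batch-export lines from a search result
#'
#' One document per line; batch exports never include seed batches.
#'
#' @param db A `seed_db`.
#' @param lines Character vector of line ids or names (non-empty).
#' @return A list of `interchange_document`s.
#' @export
export_lines_batch <- function(db, lines) {
  if (length(lines) == 0L) {
    sl_abort("validation_error", "no lines selected for export")
  }
  lapply(lines, function(l) export_line(db, l, batches = NULL))
}

#' Write / read an interchange document
#'
#' @param doc An `interchange_document`.
#' @param path File path (`.json`).
#' @return `write_interchange()` the path invisibly; `read_interchange()` the
#'   document (validated).
#' @export
write_interchange <- function(doc, path) {
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_interchange
#' @export
read_interchange <- function(path) {
  if (!file.exists(path)) {
    sl_abort("not_found_error", sprintf("no file at '%s'", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_interchange(doc)
  class(doc) <- "interchange_document"
  doc
}

#' Validate an interchange document
#'
#' Structural validation against the shipped format (version 1). Errors name
#' the offending location as a JSON pointer.
#'
#' @param doc A parsed document (list).
#' @return Invisibly `TRUE`; otherwise a format error.
#' @export
validate_interchange <- function(doc) {
  fail <- function(pointer, why) {
    sl_abort("format_error",
             sprintf("invalid interchange document at %s: %s", pointer, why),
             pointer = pointer)
  }
  need <- function(x, field, pointer, type = "character") {
    v <- x[[field]]
    p <- paste0(pointer, "/", field)
    if (is.null(v)) fail(p, "missing")
    if (type == "character" && !is.character(v)) fail(p, "must be text")
    if (type == "list" && !is.list(v)) fail(p, "must be an object/array")
    v
  }
  if (!is.list(doc)) fail("", "document is not a JSON object")
  ver <- need(doc, "format_version", "")
  if (!identical(ver, INTERCHANGE_VERSION)) {
    fail("/format_version", sprintf("unsupported version '%s'", ver))
  }
  line <- need(doc, "line", "", "list")
  need(line, "name", "/line")
  need(line, "species", "/line")
  need(line, "ecotype", "/line")
  mta <- need(line, "mta", "/line", "list")
  if (!is.logical(mta$protected)) fail("/line/mta/protected", "must be boolean")
  feats <- doc$features
  if (!is.null(feats) && !is.list(feats)) fail("/features", "must be an array")
  for (i in seq_along(feats)) {
    p <- sprintf("/features/%d", i - 1L)
    d <- need(feats[[i]], "designation", p)
    if (!nzchar(d)) fail(paste0(p, "/designation"), "must be non-empty")
    cat_ <- need(feats[[i]], "category", p)
    if (!cat_ %in% feature_categories()) {
      fail(paste0(p, "/category"),
           sprintf("must be one of %s", paste(feature_categories(), collapse = ", ")))
    }
  }
  for (i in seq_along(doc$seed_batches)) {
    p <- sprintf("/seed_batches/%d", i - 1L)
    pid <- need(doc$seed_batches[[i]], "personal_identifier", p)
    if (!nzchar(pid)) fail(paste0(p, "/personal_identifier"), "must be non-empty")
    mp <- doc$seed_batches[[i]]$mother_plant
    if (!is.null(mp) &&
        (!is.numeric(mp) || mp < 1 || mp > length(doc$mother_plants))) {
      fail(paste0(p, "/mother_plant"), "must index an entry of /mother_plants")
    }
  }
  for (i in seq_along(doc$mother_plants)) {
    p <- sprintf("/mother_plants/%d", i - 1L)
    need(doc$mother_plants[[i]], "personal_identifier", p)
  }
  invisible(TRUE)
}

#' Import a plant line from an interchange document
#'
#' Creates a line with creation mode `IMPORT` and no parents (all parental
#' links are severed). Every feature in the document becomes an owned feature
#' of the new line, its provenance text preserved. The embedded genealogy
#' image is stored as a "file from source" attachment. An ecotype absent from
#' the vocabulary is mapped to `"(Other)"` with a warning; unknown species,
#' mutation methods, method references, strains or resistances abort the
#' import with a report of the values an administrator must create — unless
#' `map_unknown` supplies substitutes.
#'
#' @param db A `seed_db`.
#' @param doc An `interchange_document` (or path to one).
#' @param new_name Name of the new database entry (mandatory).
#' @param person Responsible person for the imported line (a `PERSON`
#'   vocabulary value); person fields are redacted on export, so the importer
#'   supplies one (defaults to none).
#' @param map_unknown Named character vector/list mapping unknown vocabulary
#'   values to existing ones, e.g.
#'   `c("T-DNA (their lab)" = "T-DNA")`.
#' @return The new line record, invisibly.
#' @export
import_line <- function(db, doc, new_name, person = NULL,
                        map_unknown = list()) {
  sl_require_role(db, "WRITER")
  if (is.character(doc)) doc <- read_interchange(doc)
  validate_interchange(doc)
  if (missing(new_name) || is.null(new_name) || !nzchar(new_name)) {
    sl_abort("validation_error",
             "a name must be specified for the new database entry")
  }
  map_unknown <- as.list(map_unknown)
  map1 <- function(v) {
    if (!is.null(v) && !is.null(map_unknown[[v]])) map_unknown[[v]] else v
  }

  # collect every vocabulary value the document needs, report unknowns at once
  unknown <- character()
  check_vocab <- function(category, value) {
    if (is.null(value)) return(NULL)
    value <- map1(value)
    v <- sl_vocab_find(db, category, value)
    if (is.null(v)) {
      unknown <<- c(unknown, sprintf("%s '%s'", category, value))
      return(NULL)
    }
    v$value
  }
  species <- check_vocab("SPECIES", doc$line$species)
  for (f in doc$features) {
    check_vocab("MUTATION_METHOD", f$mutation_method)
    check_vocab("METHOD_REFERENCE", f$method_reference)
    check_vocab("RESISTANCE", f$selectable_resistance)
    check_vocab("STRAIN", f$agro_strain)
  }
  if (length(unknown) > 0L) {
    sl_abort("vocabulary_error",
             sprintf(paste("the document uses options missing from this database:",
                           "%s. An administrator must create the corresponding",
                           "choices (or supply map_unknown= substitutes)."),
                     paste(unique(unknown), collapse = "; ")),
             unknown_values = unique(unknown))
  }

  species_id <- sl_vocab_find(db, "SPECIES", species)$id
  ecotype <- map1(doc$line$ecotype)
  eco <- sl_ecotype_find(db, ecotype, species_id)
  if (is.null(eco)) {
    warning(sprintf("ecotype '%s' is not registered for species '%s'; imported as '%s'",
                    ecotype, species, OTHER_ECOTYPE), call. = FALSE)
    ecotype <- OTHER_ECOTYPE
  } else {
    ecotype <- eco$value
  }

  files <- lapply(doc$line$files_from_source, sl_de_attachment)
  if (!is.null(doc$tree_image)) {
    files <- c(files, list(sl_de_attachment(doc$tree_image)))
  }
  person_id <- sl_vocab_ref(db, "PERSON", person, "person")
  line <- sl_new_line(
    db, name = new_name, person = person_id, species = species_id,
    ecotype_label = ecotype, origin = doc$line$origin %||% "",
    creation_mode = "IMPORT", parents = list(),
    mta = sl_mta(isTRUE(doc$line$mta$protected), ""),
    files_from_source = files
  )

  # all features become OWNED by the imported line; provenance text survives
  new_fids <- character(length(doc$features))
  for (i in seq_along(doc$features)) {
    f <- doc$features[[i]]
    frec <- add_feature(
      db, line$id, category = f$category, designation = f$designation,
      gene = f$gene %||% "",
      mutation_method = map1(f$mutation_method),
      method_reference = map1(f$method_reference),
      sequence = f$sequence %||% "",
      selectable_resistance = if (f$category == "TRANSGENESIS") {
        map1(f$selectable_resistance)
      },
      agro_strain = if (f$category == "TRANSGENESIS") map1(f$agro_strain),
      genotyping_protocol = f$genotyping_protocol %||% "",
      protocol_attachments = lapply(f$protocol_attachments, sl_de_attachment)
    )
    db$features[[frec$id]]$provenance <- f$provenance %||% ""
    new_fids[i] <- frec$id
  }
  rekey <- function(m) {
    if (length(m) == 0L) return(list())
    stats::setNames(m, new_fids[as.integer(names(m))])
  }

  mother_map <- character(length(doc$mother_plants))
  for (i in seq_along(doc$mother_plants)) {
    p <- doc$mother_plants[[i]]
    prec <- add_plant(
      db, line$id, personal_identifier = p$personal_identifier,
      generation_label = p$generation_label %||% "",
      genotypes = rekey(p$genotypes),
      phenotype_note = p$phenotype_note %||% "",
      attachments = lapply(p$attachments, sl_de_attachment)
    )
    sites <- rekey(p$insertion_sites)
    for (fid in names(sites)) set_insertion_sites(db, prec$id, fid, sites[[fid]])
    mother_map[i] <- prec$id
  }

  for (b in doc$seed_batches) {
    add_seed_batch(
      db, line$id, personal_identifier = b$personal_identifier,
      generation_label = b$generation_label %||% "",
      mother_plant = if (!is.null(b$mother_plant)) mother_map[[b$mother_plant]],
      segregation = rekey(b$segregation),
      harvest_date = b$harvest_date %||% "",
      germination_result = b$germination_result %||% "",
      germination_attachments = lapply(b$germination_attachments,
                                       sl_de_attachment),
      phenotype_note = b$phenotype_note %||% "",
      phenotype_attachments = lapply(b$phenotype_attachments, sl_de_attachment)
    )
  }
  sl_log(db, "import_line", paste(line$id, new_name))
  invisible(db$lines[[line$id]])
}
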