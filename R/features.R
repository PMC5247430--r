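# Genetic features: one mutation or transgene each, owned by exactly one
# origin line and inherited by descendants BY REFERENCE. Category TRANSGENESIS
# (transgene insertion: T-DNA, transposon — rendered green, flags the line as
# GMO) or ENDOGENOUS (sequence change of a native locus — rendered blue).

#' Add a genetic feature to a line
#'
#' The feature becomes an owned (non-inherited) feature of `line`, with
#' `line` as its immutable origin. Only the designation is mandatory. A
#' CRISPR/TALEN/ZFN event is modeled as two features on the same line: a
#' TRANSGENESIS feature for the editing-machinery T-DNA and an ENDOGENOUS
#' feature for the targeted locus.
#'
#' @param db A `seed_db`.
#' @param line Line id or name; must be the feature's origin (adding through a
#'   descendant is refused).
#' @param category `"TRANSGENESIS"` or `"ENDOGENOUS"`.
#' @param designation Mutation/transgene name, e.g. `"Pro35S:GUS"` — the only
#'   mandatory field.
#' @param gene Gene name.
#' @param mutation_method A `MUTATION_METHOD` vocabulary value whose declared
#'   feature category must equal `category`.
#' @param method_reference A `METHOD_REFERENCE` vocabulary value.
#' @param sequence Transgene sequence (TRANSGENESIS) or mutated-locus
#'   sequence (ENDOGENOUS).
#' @param selectable_resistance,agro_strain `RESISTANCE` / `STRAIN`
#'   vocabulary values; TRANSGENESIS features only.
#' @param genotyping_protocol Free-text protocol (PCR primers, program, ...).
#' @param protocol_attachments List of [attachment()]s (e.g. a gel picture).
#' @return The new feature record, invisibly.
#' @export
add_feature <- function(db, line, category, designation, gene = "",
                        mutation_method = NULL, method_reference = NULL,
                        sequence = "", selectable_resistance = NULL,
                        agro_strain = NULL, genotyping_protocol = "",
                        protocol_attachments = list()) {
  sl_require_role(db, "WRITER")
  rec <- sl_get_line(db, line)
  sl_check_unlocked(rec, "line")
  category <- match.arg(toupper(category), feature_categories())
  if (is.null(designation) || !nzchar(designation)) {
    sl_abort("validation_error",
             "a genetic feature requires a designation (mutation name)")
  }
  if (any(vapply(rec$features,
                 function(fid) identical(db$features[[fid]]$designation, designation),
                 logical(1)))) {
    warning(sprintf("line '%s' already owns a feature designated '%s'",
                    rec$name, designation), call. = FALSE)
  }
  method_id <- sl_vocab_ref(db, "MUTATION_METHOD", mutation_method, "mutation method")
  if (!is.null(method_id)) {
    mcat <- db$vocab[[method_id]]$feature_category
    if (!identical(mcat, category)) {
      sl_abort("category_error",
               sprintf("mutation method '%s' produces %s features, not %s",
                       mutation_method, mcat, category))
    }
  }
  if (category != "TRANSGENESIS" &&
      (!is.null(selectable_resistance) || !is.null(agro_strain))) {
    sl_abort("category_error",
             "resistance and Agrobacterium strain apply to TRANSGENESIS features only")
  }
  id <- sl_next_id(db, "feature", "F")
  db$features[[id]] <- list(
    id = id, designation = designation, category = category,
    origin_line = rec$id, provenance = "",
    gene = gene, mutation_method = method_id,
    method_reference = sl_vocab_ref(db, "METHOD_REFERENCE", method_reference,
                                    "method reference"),
    sequence = sequence,
    selectable_resistance = sl_vocab_ref(db, "RESISTANCE",
                                         selectable_resistance, "resistance"),
    agro_strain = sl_vocab_ref(db, "STRAIN", agro_strain, "strain"),
    genotyping_protocol = genotyping_protocol,
    protocol_attachments = protocol_attachments,
    locked = FALSE
  )
  db$lines[[rec$id]]$features <- c(db$lines[[rec$id]]$features, id)
  sl_log(db, "add_feature", paste(rec$id, id, designation))
  invisible(db$features[[id]])
}

#' Edit a genetic feature through its origin line
#'
#' Features are stored once and inherited by reference: edits are only
#' permitted through the origin line, and every descendant sees the change
#' immediately. An edit attempted through a descendant line raises an
#' immutability error regardless of lock state.
#'
#' @param db A `seed_db`.
#' @param line The line through which the edit is attempted.
#' @param feature Feature id.
#' @param designation,gene,sequence,genotyping_protocol New values (omit to
#'   keep).
#' @return The updated record, invisibly.
#' @export
edit_feature <- function(db, line, feature, designation = NULL, gene = NULL,
                         sequence = NULL, genotyping_protocol = NULL) {
  sl_require_role(db, "WRITER")
  lrec <- sl_get_line(db, line)
  frec <- sl_get_feature(db, feature)
  if (!identical(frec$origin_line, lrec$id)) {
    eff <- sl_effective_feature_ids(db, lrec$id)
    if (frec$id %in% eff) {
      sl_abort("immutability_error",
               sprintf(paste("feature '%s' is inherited from line '%s';",
                             "inherited properties cannot be modified —",
                             "edit the parental line instead"),
                       frec$designation, db$lines[[frec$origin_line]]$name))
    }
    sl_abort("consistency_error",
             sprintf("feature '%s' does not belong to line '%s'",
                     frec$id, lrec$name))
  }
  sl_check_unlocked(frec, "feature")
  if (!is.null(designation)) {
    if (!nzchar(designation)) {
      sl_abort("validation_error", "designation must be non-empty")
    }
    frec$designation <- designation
  }
  if (!is.null(gene)) frec$gene <- gene
  if (!is.null(sequence)) frec$sequence <- sequence
  if (!is.null(genotyping_protocol)) frec$genotyping_protocol <- genotyping_protocol
  db$features[[frec$id]] <- frec
  sl_log(db, "edit_feature", frec$id)
  invisible(frec)
}
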