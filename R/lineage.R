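# Pedigree operations. Lines form a DAG through their parent links (parents
# must pre-exist, imports sever links, so cycles cannot arise). A line's
# EFFECTIVE feature set is its owned features plus, by reference, the union
# of its parents' effective sets — the single stored copy of each feature
# means an edit on the origin line is instantly visible in every descendant.

# owned + inherited feature ids: parents' features first, then own. A
# visited set keeps the walk linear on dense pedigrees where ancestors are
# shared between both sides of a cross.
sl_effective_feature_ids <- function(db, line_id) {
  seen_lines <- character()
  ids <- character()
  walk <- function(id) {
    if (id %in% seen_lines) return(invisible(NULL))
    seen_lines <<- c(seen_lines, id)
    for (p in db$lines[[id]]$parents) walk(p$line)
    ids <<- c(ids, db$lines[[id]]$features)
  }
  walk(line_id)
  unique(ids)
}

sl_parent_ids <- function(rec) vapply(rec$parents, `[[`, character(1), "line")

sl_children <- function(db, line_id) {
  kids <- character()
  for (l in db$lines) {
    if (line_id %in% sl_parent_ids(l)) kids <- c(kids, l$id)
  }
  kids
}

#' Effective genetic features of a line
#'
#' The feature table of the datasheet: owned features plus all features
#' inherited from parental lines. Inherited features are labeled
#' `"from <origin line name>"` (the label tracks renames, because features
#' are stored once and referenced) and are read-only through this line. The
#' color class — GREEN for TRANSGENESIS, BLUE for ENDOGENOUS — gives the
#' at-a-glance GMO/non-GMO distinction.
#'
#' @param db A `seed_db`.
#' @param line Line id or name.
#' @return A data frame with one row per effective feature: `feature_id`,
#'   `designation`, `category`, `color`, `origin_line`, `origin_label`
#'   (`""` for owned features), `inherited`.
#' @export
effective_features <- function(db, line) {
  rec <- sl_get_line(db, line)
  ids <- sl_effective_feature_ids(db, rec$id)
  rows <- lapply(ids, function(fid) {
    f <- db$features[[fid]]
    inherited <- !identical(f$origin_line, rec$id)
    data.frame(
      feature_id = fid,
      designation = f$designation,
      category = f$category,
      color = if (f$category == "TRANSGENESIS") "GREEN" else "BLUE",
      origin_line = f$origin_line,
      origin_label = if (inherited) {
        paste0("from ", db$lines[[f$origin_line]]$name)
      } else f$provenance %||% "",  # imported features keep provenance text
      inherited = inherited,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(feature_id = character(), designation = character(),
                      category = character(), color = character(),
                      origin_line = character(), origin_label = character(),
                      inherited = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Is a line transgene-bearing (GMO)?
#'
#' A line is GMO iff at least one effective feature has category
#' TRANSGENESIS — i.e. iff its feature table contains a GREEN box.
#'
#' @inheritParams effective_features
#' @return Logical.
#' @export
is_gmo <- function(db, line) {
  any(effective_features(db, line)$category == "TRANSGENESIS")
}

# validate a feature-spec list for cross/mutag wizards
sl_check_feature_spec <- function(spec) {
  if (is.null(spec$designation) || !nzchar(spec$designation)) {
    sl_abort("validation_error",
             "the new genetic feature requires a designation (mutation name)")
  }
  if (is.null(spec$category)) {
    sl_abort("validation_error", "the new genetic feature requires a category")
  }
  spec$category <- match.arg(toupper(spec$category), feature_categories())
  spec
}

sl_add_feature_from_spec <- function(db, line_id, spec) {
  do.call(add_feature, c(list(db = db, line = line_id,
                              category = spec$category,
                              designation = spec$designation),
                         spec[setdiff(names(spec), c("category", "designation"))]))
}

#' Cross two recorded plant lines
#'
#' Creates the child line of an intra-species cross: its effective feature
#' set is the union of both parents' effective sets, inherited by reference
#' and read-only through the child. When the parents' ecotypes differ the
#' child carries the combined label `"<female> x <male>"`. The seed batches
#' used for the cross can be recorded on the parent edges. For pollen
#' mutagenesis — a cross combined with an additional mutagenesis — one extra
#' feature can be added during the cross; it is owned by the child.
#'
#' @param db A `seed_db`.
#' @param female,male Parent lines (ids or names); must be of the same
#'   species and distinct (selfing stays within one line as new
#'   plants/batches).
#' @param female_batch,male_batch Optional system ids of the seed batches
#'   used; each must belong to its parent.
#' @param extra_feature Optional feature spec,
#'   `list(category =, designation =, ...)`, owned by the child.
#' @param name Child line name; defaults to `"<female> x <male>"`.
#' @param person Responsible person; defaults to the female parent's.
#' @return The new line record, invisibly.
#' @export
cross_lines <- function(db, female, male, female_batch = NULL,
                        male_batch = NULL, extra_feature = NULL,
                        name = NULL, person = NULL) {
  sl_require_role(db, "WRITER")
  f <- sl_get_line(db, female)
  m <- sl_get_line(db, male)
  if (identical(f$id, m$id)) {
    sl_abort("consistency_error",
             "self-crosses are not recorded as new lines; add plants or seed batches to the line instead")
  }
  if (!identical(f$species, m$species)) {
    sl_abort("species_error",
             sprintf("only intra-species crosses are permitted ('%s' is %s, '%s' is %s)",
                     f$name, sl_vocab_value(db, f$species),
                     m$name, sl_vocab_value(db, m$species)))
  }
  sl_check_parent_batch(db, f, female_batch)
  sl_check_parent_batch(db, m, male_batch)
  if (!is.null(extra_feature)) extra_feature <- sl_check_feature_spec(extra_feature)

  eco <- if (tolower(f$ecotype_label) == tolower(m$ecotype_label)) {
    f$ecotype_label
  } else {
    paste(f$ecotype_label, "x", m$ecotype_label)
  }
  person_id <- if (is.null(person)) f$person else sl_vocab_ref(db, "PERSON", person, "person")
  child <- sl_new_line(
    db,
    name = name %||% paste(f$name, "x", m$name),
    person = person_id, species = f$species, ecotype_label = eco,
    origin = "", creation_mode = "CROSS",
    parents = list(
      sl_parent_edge("FEMALE", f$id, sl_batch_id(female_batch)),
      sl_parent_edge("MALE", m$id, sl_batch_id(male_batch))
    ),
    mta = sl_mta(FALSE)
  )
  if (!is.null(extra_feature)) sl_add_feature_from_spec(db, child$id, extra_feature)
  invisible(db$lines[[child$id]])
}

sl_batch_id <- function(batch) {
  if (is.null(batch)) return(NULL)
  as.integer(if (is.list(batch)) batch$system_id else batch)
}

# the batch key is present only when a batch was recorded, so in-memory and
# JSON-reloaded registries are structurally identical
sl_parent_edge <- function(role, line_id, batch = NULL) {
  e <- list(role = role, line = line_id)
  if (!is.null(batch)) e$batch <- batch
  e
}

sl_check_parent_batch <- function(db, parent, batch) {
  if (is.null(batch)) return(invisible(TRUE))
  b <- sl_get_batch(db, batch)
  if (!identical(b$line, parent$id)) {
    sl_abort("consistency_error",
             sprintf("seed batch %d does not belong to parent line '%s'",
                     b$system_id, parent$name))
  }
  invisible(TRUE)
}

#' Apply a secondary mutagenesis to a recorded line
#'
#' Creates the child line of a new mutagenesis/transformation applied to an
#' existing (possibly already mutant) line. The child inherits the species,
#' ecotype and every genetic feature of the mother line by reference, and
#' owns exactly the one new feature.
#'
#' @param db A `seed_db`.
#' @param parent The mother line (id or name).
#' @param feature Feature spec of the new mutation:
#'   `list(category =, designation =, ...)`.
#' @param name Child line name; defaults to
#'   `"<parent> <designation>"`.
#' @param person Responsible person; defaults to the parent's.
#' @return The new line record, invisibly.
#' @export
mutagenize_line <- function(db, parent, feature, name = NULL, person = NULL) {
  sl_require_role(db, "WRITER")
  p <- sl_get_line(db, parent)
  feature <- sl_check_feature_spec(feature)
  person_id <- if (is.null(person)) p$person else sl_vocab_ref(db, "PERSON", person, "person")
  child <- sl_new_line(
    db,
    name = name %||% paste(p$name, feature$designation),
    person = person_id, species = p$species, ecotype_label = p$ecotype_label,
    origin = "", creation_mode = "MUTAG",
    parents = list(sl_parent_edge("MOTHER", p$id)),
    mta = sl_mta(FALSE)
  )
  sl_add_feature_from_spec(db, child$id, feature)
  invisible(db$lines[[child$id]])
}

#' Ancestry graph of a line
#'
#' Builds the genealogy shown on the datasheet: the line and all its
#' transitive parents, with edges directed parent -> child. Edge attributes
#' carry the parental role (`FEMALE`/`MALE`/`MOTHER`) and, when recorded,
#' the system id of the seed batch used. Vertex attributes carry the line
#' name, its MTA flag (protected lines are flagged red in renderings) and
#' creation mode.
#'
#' @inheritParams effective_features
#' @return An [igraph::graph] object; a line without parents yields a single
#'   vertex and no edges.
#' @export
ancestry_tree <- function(db, line) {
  rec <- sl_get_line(db, line)
  nodes <- character()
  edges <- list()
  walk <- function(id) {
    if (id %in% nodes) return(invisible(NULL))
    nodes <<- c(nodes, id)
    for (p in db$lines[[id]]$parents) {
      walk(p$line)
      edges[[length(edges) + 1L]] <<- list(from = p$line, to = id,
                                           role = p$role,
                                           batch = p$batch %||% NA_integer_)
    }
  }
  walk(rec$id)
  # vertices in creation order for deterministic output
  nodes <- nodes[order(as.integer(sub("^L", "", nodes)))]
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(
    g, length(nodes), name = nodes,
    label = vapply(nodes, function(i) db$lines[[i]]$name, character(1)),
    mta = vapply(nodes, function(i) isTRUE(db$lines[[i]]$mta$protected), logical(1)),
    creation_mode = vapply(nodes, function(i) db$lines[[i]]$creation_mode, character(1))
  )
  for (e in edges) {
    g <- igraph::add_edges(g, c(e$from, e$to), role = e$role, batch = e$batch)
  }
  g
}

#' Number of descendant lines
#'
#' Counts the distinct lines transitively derived from this line through
#' crosses and secondary mutageneses (the line itself excluded).
#'
#' @inheritParams effective_features
#' @return Non-negative integer.
#' @export
descendant_count <- function(db, line) {
  rec <- sl_get_line(db, line)
  seen <- character()
  frontier <- rec$id
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, sl_children, db = db)))
    nxt <- setdiff(nxt, c(seen, rec$id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen)
}

#' MTA constraints bearing on a line
#'
#' A Material Transfer Agreement constrains the protected line and all its
#' progeny through every successive amplification, cross and mutagenesis.
#' This returns the MTA-protected lines among the line's ancestors (the line
#' itself included); an empty result means the material is unencumbered.
#'
#' @inheritParams effective_features
#' @return Character vector of line ids, in pedigree discovery order.
#' @export
mta_affected_set <- function(db, line) {
  rec <- sl_get_line(db, line)
  anc <- character()
  walk <- function(id) {
    if (id %in% anc) return(invisible(NULL))
    anc <<- c(anc, id)
    for (p in db$lines[[id]]$parents) walk(p$line)
  }
  walk(rec$id)
  anc[vapply(anc, function(i) isTRUE(db$lines[[i]]$mta$protected), logical(1))]
}

# ---- DOT rendering ---------------------------------------------------------

sl_dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}

sl_tree_dot <- function(db, line) {
  g <- ancestry_tree(db, line)
  nodes <- igraph::V(g)$name
  lines_out <- c("digraph genealogy {",
                 "  rankdir=BT;",  # parents at the bottom of the tree
                 "  node [shape=box];")
  for (i in seq_along(nodes)) {
    attrs <- sprintf("label=%s", sl_dot_quote(igraph::V(g)$label[i]))
    if (igraph::V(g)$mta[i]) {
      attrs <- paste0(attrs, ', style=filled, fillcolor=red')
    }
    lines_out <- c(lines_out,
                   sprintf("  %s [%s];", sl_dot_quote(nodes[i]), attrs))
  }
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    for (i in seq_len(nrow(el))) {
      lbl <- tolower(igraph::E(g)$role[i])
      b <- igraph::E(g)$batch[i]
      if (!is.na(b)) lbl <- sprintf("%s (batch %d)", lbl, as.integer(b))
      lines_out <- c(lines_out,
                     sprintf("  %s -> %s [label=%s];",
                             sl_dot_quote(el[i, 1]), sl_dot_quote(el[i, 2]),
                             sl_dot_quote(lbl)))
    }
  }
  paste(c(lines_out, "}"), collapse = "\n")
}

#' Export the genealogy of a line
#'
#' Emits the ancestry DAG as Graphviz DOT text (deterministic: nodes in line
#' creation order; MTA-protected lines filled red; edges labeled with the
#' parental role and the seed batch used, when recorded; parents rank at the
#' bottom via `rankdir`). PNG output requires an external Graphviz renderer
#' (`dot` on the PATH); without one, a degraded-mode error suggests DOT.
#'
#' @inheritParams effective_features
#' @param format `"DOT"` or `"PNG"`.
#' @param file Output path; for DOT, `NULL` returns the text without writing.
#' @return The DOT text (invisibly when written to a file).
#' @export
export_tree <- function(db, line, format = c("DOT", "PNG"), file = NULL) {
  format <- match.arg(toupper(format), c("DOT", "PNG"))
  dot <- sl_tree_dot(db, line)
  if (format == "DOT") {
    if (is.null(file)) return(dot)
    writeLines(dot, file)
    return(invisible(dot))
  }
  renderer <- Sys.which("dot")
  if (!nzchar(renderer)) {
    sl_abort("degraded_error",
             "no Graphviz renderer available for PNG; export as DOT instead")
  }
  if (is.null(file)) {
    sl_abort("validation_error", "PNG export requires an output file path")
  }
  tmp <- tempfile(fileext = ".gv")
  on.exit(unlink(tmp))
  writeLines(dot, tmp)
  status <- system2(renderer, c("-Tpng", "-o", shQuote(file), shQuote(tmp)))
  if (!identical(status, 0L)) {
    sl_abort("degraded_error", "PNG rendering failed; export as DOT instead")
  }
  invisible(dot)
}
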