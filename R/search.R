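# Search engine: a generic keyword field matched against line names, gene
# names and feature designations, plus per-section criteria addressing the
# four searchable datasheet sections. Patterns use SQL-LIKE-style wildcards:
#   %   any run of characters (including none)
#   _   exactly one character
#   $%  literal '%',  $_  literal '_'  ($ followed by any other character is
#       that literal character pair)
# Without wildcards a pattern matches the whole value exactly. Matching is
# case-insensitive throughout.

#' Compile a wildcard pattern into a matcher
#'
#' @param pattern Pattern text (non-empty). A trailing bare `$` is an error.
#' @return A function `f(values)` returning a logical vector of whole-value,
#'   case-insensitive matches; the translated regular expression is attached
#'   as attribute `"regex"`.
#' @examples
#' m <- compile_pattern("pht1;_")
#' m(c("pht1;1", "pht1;11"))   # TRUE FALSE
#' compile_pattern("50$%")("50%")  # TRUE
#' @export
compile_pattern <- function(pattern) {
  if (is.null(pattern) || !nzchar(pattern)) {
    sl_abort("pattern_error", "pattern must be non-empty")
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  rx <- character()
  i <- 1L
  n <- length(chars)
  esc <- function(ch) {
    if (grepl("[][{}()*+?.\\^$|-]", ch)) paste0("\\", ch) else ch
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "$") {
      if (i == n) {
        sl_abort("pattern_error",
                 "trailing '$' in pattern: '$' must be followed by a character")
      }
      rx <- c(rx, esc(chars[i + 1L]))
      i <- i + 2L
    } else if (ch == "%") {
      rx <- c(rx, ".*")
      i <- i + 1L
    } else if (ch == "_") {
      rx <- c(rx, ".")
      i <- i + 1L
    } else {
      rx <- c(rx, esc(ch))
      i <- i + 1L
    }
  }
  regex <- paste0("^", paste(rx, collapse = ""), "$")
  f <- function(values) {
    if (length(values) == 0L) return(logical(0))
    !is.na(values) & grepl(regex, values, ignore.case = TRUE, perl = TRUE)
  }
  attr(f, "regex") <- regex
  f
}

# searchable fields, grouped by datasheet section
SEARCH_FIELDS <- list(
  general = c("name", "species", "ecotype", "origin", "person"),
  feature = c("designation", "gene", "category", "mutation_method"),
  plant = c("personal_identifier", "generation", "person"),
  batch = c("personal_identifier", "generation", "system_id",
            "storage_place", "person")
)

#' Valid search criteria field names
#'
#' Criteria address fields as `"<section>.<field>"`; this lists the valid
#' combinations.
#'
#' @return Character vector like `"general.name"`, `"batch.system_id"`.
#' @export
search_fields <- function() {
  unlist(lapply(names(SEARCH_FIELDS), function(s) {
    paste(s, SEARCH_FIELDS[[s]], sep = ".")
  }), use.names = FALSE)
}

# candidate values of one field on one line (vector: a criterion matches when
# it matches the line's value or at least one of its plants'/batches' values)
sl_field_values <- function(db, line_rec, section, field) {
  eff <- function() effective_features(db, line_rec$id)
  switch(
    section,
    general = switch(field,
      name = line_rec$name,
      species = sl_vocab_value(db, line_rec$species),
      ecotype = line_rec$ecotype_label,
      origin = line_rec$origin,
      person = sl_vocab_value(db, line_rec$person) %||% ""
    ),
    feature = {
      tab <- eff()
      switch(field,
        designation = tab$designation,
        gene = vapply(tab$feature_id,
                      function(fid) db$features[[fid]]$gene %||% "", character(1)),
        category = tab$category,
        mutation_method = vapply(tab$feature_id, function(fid) {
          sl_vocab_value(db, db$features[[fid]]$mutation_method) %||% ""
        }, character(1))
      )
    },
    plant = {
      ps <- Filter(function(p) identical(p$line, line_rec$id), db$plants)
      switch(field,
        personal_identifier = vapply(ps, `[[`, character(1), "personal_identifier"),
        generation = vapply(ps, `[[`, character(1), "generation_label"),
        person = vapply(ps, function(p) sl_vocab_value(db, p$person) %||% "",
                        character(1))
      )
    },
    batch = {
      bs <- Filter(function(b) identical(b$line, line_rec$id), db$batches)
      switch(field,
        personal_identifier = vapply(bs, `[[`, character(1), "personal_identifier"),
        generation = vapply(bs, `[[`, character(1), "generation_label"),
        system_id = vapply(bs, function(b) as.character(b$system_id), character(1)),
        storage_place = vapply(bs, `[[`, character(1), "storage_place"),
        person = vapply(bs, function(b) sl_vocab_value(db, b$person) %||% "",
                        character(1))
      )
    }
  )
}

#' Search plant lines
#'
#' The generic pattern matches a line when it matches ANY of the line name,
#' a gene name, or a feature designation (over the line's effective
#' features). Each section criterion (named `"<section>.<field>"`, see
#' [search_fields()]) must additionally match the line's value of that field,
#' or the value on at least one of the line's plants/batches; criteria
#' combine as AND at the line level. Results are ordered by line name.
#'
#' @param db A `seed_db`.
#' @param generic Optional generic pattern.
#' @param criteria Named list of `"<section>.<field>" = pattern`.
#' @param show_all Return all lines (no criteria needed).
#' @return A data frame with `line_id`, `name`, `species`, `ecotype`,
#'   `n_features`, ordered by `name`.
#' @export
search_lines <- function(db, generic = NULL, criteria = list(),
                         show_all = FALSE) {
  if (!show_all && is.null(generic) && length(criteria) == 0L) {
    sl_abort("validation_error",
             "give at least one criterion, or request all lines")
  }
  bad <- setdiff(names(criteria), search_fields())
  if (length(bad) > 0L) {
    sl_abort("field_error",
             sprintf("unknown search field(s): %s; valid fields are: %s",
                     paste(bad, collapse = ", "),
                     paste(search_fields(), collapse = ", ")))
  }
  gm <- if (!is.null(generic)) compile_pattern(generic)
  cms <- lapply(criteria, compile_pattern)

  hits <- Filter(function(l) {
    if (!is.null(gm)) {
      tab <- effective_features(db, l$id)
      genes <- vapply(tab$feature_id,
                      function(fid) db$features[[fid]]$gene %||% "", character(1))
      cand <- c(l$name, genes, tab$designation)
      if (!any(gm(cand))) return(FALSE)
    }
    for (key in names(cms)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      vals <- sl_field_values(db, l, parts[1], parts[2])
      if (!any(cms[[key]](vals))) return(FALSE)
    }
    TRUE
  }, db$lines)

  out <- data.frame(
    line_id = vapply(hits, `[[`, character(1), "id"),
    name = vapply(hits, `[[`, character(1), "name"),
    species = vapply(hits, function(l) sl_vocab_value(db, l$species), character(1)),
    ecotype = vapply(hits, `[[`, character(1), "ecotype_label"),
    n_features = vapply(hits, function(l) {
      length(sl_effective_feature_ids(db, l$id))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$name), , drop = FALSE]
}
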