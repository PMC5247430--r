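# Independent brute-force oracles. Each deliberately takes a different route
# than the implementation: the wildcard oracle is a recursive char-by-char
# matcher (the package translates to a regex); the feature oracle unions the
# OWNED features over the ancestor closure (the package does a parent-first
# DFS); descendants are found by scanning every line's ancestor set.

# recursive wildcard matcher, case-insensitive whole-value match
bf_match <- function(pattern, value) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tok <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "$") {
      stopifnot(i < length(chars))
      tok[[length(tok) + 1L]] <- list(kind = "lit", ch = tolower(chars[i + 1L]))
      i <- i + 2L
    } else if (ch == "%") {
      tok[[length(tok) + 1L]] <- list(kind = "any"); i <- i + 1L
    } else if (ch == "_") {
      tok[[length(tok) + 1L]] <- list(kind = "one"); i <- i + 1L
    } else {
      tok[[length(tok) + 1L]] <- list(kind = "lit", ch = tolower(ch))
      i <- i + 1L
    }
  }
  v <- strsplit(tolower(value), "", fixed = TRUE)[[1]]
  rec <- function(ti, vi) {
    if (ti > length(tok)) return(vi > length(v))
    t <- tok[[ti]]
    if (t$kind == "any") {
      for (k in vi:(length(v) + 1L)) if (rec(ti + 1L, k)) return(TRUE)
      return(FALSE)
    }
    if (vi > length(v)) return(FALSE)
    if (t$kind == "one") return(rec(ti + 1L, vi + 1L))
    identical(t$ch, v[vi]) && rec(ti + 1L, vi + 1L)
  }
  rec(1L, 1L)
}

bf_parent_ids <- function(db, id) {
  vapply(db$lines[[id]]$parents, `[[`, character(1), "line")
}

# transitive ancestor closure by frontier expansion
bf_ancestors <- function(db, id, include_self = TRUE) {
  anc <- id
  frontier <- id
  while (length(frontier) > 0L) {
    ps <- unique(unlist(lapply(frontier, bf_parent_ids, db = db)))
    ps <- setdiff(ps, anc)
    anc <- c(anc, ps)
    frontier <- ps
  }
  if (include_self) anc else setdiff(anc, id)
}

# effective features = union of OWNED features over ancestors incl. self
bf_effective <- function(db, id) {
  sort(unique(unlist(lapply(bf_ancestors(db, id), function(a) {
    db$lines[[a]]$features
  }))))
}

# descendants of id = lines that have id among their strict ancestors
bf_descendants <- function(db, id) {
  Filter(function(other) {
    !identical(other, id) && id %in% bf_ancestors(db, other, include_self = FALSE)
  }, names(db$lines))
}

bf_mta_affected <- function(db, id) {
  anc <- bf_ancestors(db, id)
  anc[vapply(anc, function(i) isTRUE(db$lines[[i]]$mta$protected), logical(1))]
}

# random wildcard pattern over a small alphabet, escapes included
random_pattern <- function() {
  pieces <- c(letters[1:6], "0", "1", "-", ";", "%", "%", "_", "$%", "$_")
  n <- sample(1:6, 1L)
  paste(sample(pieces, n, replace = TRUE), collapse = "")
}

# a small standard laboratory database used across unit tests
make_lab_db <- function() {
  db <- seed_db()
  for (p in c("alice", "bob")) add_vocab_entry(db, "PERSON", p)
  add_vocab_entry(db, "SPECIES", "Arabidopsis thaliana")
  add_vocab_entry(db, "SPECIES", "Oryza sativa")
  for (e in c("Col-0", "Ler")) {
    add_vocab_entry(db, "ECOTYPE", e, linked_species = "Arabidopsis thaliana")
  }
  add_vocab_entry(db, "ECOTYPE", "Nipponbare", linked_species = "Oryza sativa")
  db
}
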