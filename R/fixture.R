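# Seeded synthetic-pedigree generator. Emulates a working lab registry:
# founder lines of a couple of species with random features of both
# categories and random MTA protection, followed by a history of crosses
# (same-species pairs) and secondary mutageneses, with plants and seed
# batches attached at random generations. Deterministic for a given seed.

#' Generate a synthetic populated registry
#'
#' Builds a fresh database, seeds persons/species/ecotypes on top of the
#' defaults, creates `n_founders` founder lines (each with 0–2 random
#' features of random category, MTA-protected with probability `p_mta`),
#' then plays `n_events` pedigree events: each is a cross of two random
#' same-species lines with probability `p_cross` (falling back to a
#' mutagenesis when no same-species pair exists), otherwise a secondary
#' mutagenesis adding one random new feature. Every line receives 0–2 plants
#' and 0–2 seed batches with random generation labels, genotypes, storage
#' places and notebook references.
#'
#' @param n_founders Number of founder lines (>= 1).
#' @param n_events Number of cross/mutagenesis events (>= 0).
#' @param p_cross Probability that an event is a cross.
#' @param p_mta Probability that a founder is MTA-protected.
#' @param seed Integer seed; the same seed reproduces the same database.
#' @return A populated `seed_db` (administrator logged in).
#' @examples
#' db <- generate_fixture(n_founders = 3, n_events = 5, seed = 42)
#' search_lines(db, show_all = TRUE)
#' @export
generate_fixture <- function(n_founders, n_events, p_cross = 0.5,
                             p_mta = 0.1, seed = 1L) {
  if (!is.numeric(n_founders) || n_founders < 1) {
    sl_abort("validation_error", "n_founders must be at least 1")
  }
  if (!is.numeric(n_events) || n_events < 0) {
    sl_abort("validation_error", "n_events must be non-negative")
  }
  for (p in c(p_cross, p_mta)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      sl_abort("validation_error", "probabilities must lie in [0, 1]")
    }
  }

  # keep the generator deterministic without disturbing the caller's RNG
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  db <- seed_db()
  persons <- sprintf("member%02d", 1:5)
  for (p in persons) add_vocab_entry(db, "PERSON", p)
  species <- c("Arabidopsis thaliana", "Oryza sativa")
  ecotypes <- list(`Arabidopsis thaliana` = c("Col-0", "Ler", "Ws"),
                   `Oryza sativa` = c("Nipponbare", "Kasalath"))
  for (s in species) {
    add_vocab_entry(db, "SPECIES", s)
    for (e in ecotypes[[s]]) add_vocab_entry(db, "ECOTYPE", e, linked_species = s)
  }
  methods <- list(TRANSGENESIS = c("T-DNA", "Transposon"),
                  ENDOGENOUS = c("EMS", "CRISPR", "Natural variant"))
  genes <- sprintf("GENE%d", 1:12)
  fcount <- 0L

  rand_feature_spec <- function() {
    fcount <<- fcount + 1L
    cat_ <- sample(feature_categories(), 1L)
    spec <- list(
      category = cat_,
      designation = sprintf("feat-%03d", fcount),
      gene = sample(genes, 1L),
      mutation_method = sample(methods[[cat_]], 1L),
      sequence = paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                       collapse = "")
    )
    if (cat_ == "TRANSGENESIS" && stats::runif(1) < 0.5) {
      spec$selectable_resistance <- sample(c("Kanamycin", "Hygromycin", "BASTA"), 1L)
      spec$agro_strain <- sample(c("GV3101", "C58C1"), 1L)
    }
    spec
  }

  attach_material <- function(line_id) {
    eff <- sl_effective_feature_ids(db, line_id)
    for (i in seq_len(sample(0:2, 1L))) {
      g <- list()
      if (length(eff) > 0L && stats::runif(1) < 0.7) {
        picked <- sample(eff, min(length(eff), sample(1:2, 1L)))
        g <- stats::setNames(as.list(sample(genotype_states(), length(picked),
                                            replace = TRUE)), picked)
      }
      add_plant(db, line_id,
                personal_identifier = sprintf("%s-plant-%d", line_id, i),
                generation_label = sample(c("T1", "T2", "F1", "F3", "unknown"), 1L),
                genotypes = g,
                phenotype_note = sample(c("", "dwarf", "pale leaves", "wild-type like"), 1L),
                notebook_ref = sprintf("NB-%s-p%d", line_id, sample(1:99, 1L)),
                person = sample(persons, 1L))
    }
    for (i in seq_len(sample(0:2, 1L))) {
      add_seed_batch(db, line_id,
                     personal_identifier = sprintf("%s-seeds-%d", line_id, i),
                     generation_label = sample(c("T2", "T3", "F2", "unknown"), 1L),
                     harvest_date = sprintf("2025-%02d-%02d", sample(1:12, 1L),
                                            sample(1:28, 1L)),
                     storage_place = sprintf("box-%s-%02d", line_id, sample(1:40, 1L)),
                     notebook_ref = sprintf("NB-%s-s%d", line_id, sample(1:99, 1L)),
                     person = sample(persons, 1L))
    }
  }

  for (i in seq_len(n_founders)) {
    sp <- sample(species, 1L)
    ln <- create_line(db, sprintf("FND-%03d", i), sample(persons, 1L), sp,
                      ecotype = sample(ecotypes[[sp]], 1L),
                      origin = sample(c("stock center", "gift", "own transformation"), 1L))
    for (k in seq_len(sample(0:2, 1L))) {
      sl_add_feature_from_spec(db, ln$id, rand_feature_spec())
    }
    if (stats::runif(1) < p_mta) {
      set_mta(db, ln$id, TRUE,
              details = sprintf("MTA-secret-%03d recipient and terms", i))
    }
    attach_material(ln$id)
  }

  for (i in seq_len(n_events)) {
    ids <- names(db$lines)
    done <- FALSE
    if (stats::runif(1) < p_cross) {
      sp_of <- vapply(ids, function(id) db$lines[[id]]$species, character(1))
      for (sp in unique(sp_of)) {
        cand <- ids[sp_of == sp]
        if (length(cand) >= 2L) {
          pair <- sample(cand, 2L)
          ln <- cross_lines(db, pair[1], pair[2],
                            name = sprintf("CRS-%03d", i),
                            extra_feature = if (stats::runif(1) < 0.15) {
                              rand_feature_spec()  # pollen mutagenesis
                            })
          done <- TRUE
          break
        }
      }
    }
    if (!done) {
      ln <- mutagenize_line(db, sample(ids, 1L), rand_feature_spec(),
                            name = sprintf("MTG-%03d", i))
    }
    attach_material(ln$id)
  }
  db
}
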