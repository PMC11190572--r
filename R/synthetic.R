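# Synthetic description generator: emits random but valid description text
# drawn from the eight phenotype statement families (presence, absence,
# count/list, quality, absolute and relative measurement, within-species
# comparison, between-species comparison, positional), together with
# ground-truth tallies computed constructively during generation -- the
# independent oracle for compiler and query counts. Seeded mutants differ
# from the clean text by exactly one named defect.

synthetic_entity_pool <- function() {
  data.frame(
    curie = c("aism-clypeus", "aism-frons", "aism-vertex", "aism-gena",
              "aism-antenna", "aism-glossa",
              "aism-pronotum", "aism-mesoventrite", "aism-metaventrite",
              "aism-hind_wing", "colao-scutellar_shield", "aism-hypomeron",
              "aism-protibia", "aism-mesotibia", "aism-metatibia",
              "aism-profemur", "aism-metafemur", "aism-procoxa",
              "aism-abdominal_tergite_VIII", "aism-parameres",
              "colao-lamella_copulatrix", "colao-phallobase"),
    region = c(rep("head_or_part", 6), rep("thorax_or_part", 6),
               rep("leg_or_part", 6), rep("abdomen_or_part", 4)),
    stringsAsFactors = FALSE)
}

synthetic_quality_pool <- function() {
  list(
    `pato-colour` = c("pato-red_brown", "pato-dark_brown",
                      "pato-yellow_brown", "pato-red", "pato-yellow"),
    `pato-shape` = c("pato-curved", "pato-convex", "pato-concave",
                     "pato-straight", "pato-notched", "pato-obtuse",
                     "pato-tapered", "pato-elongated"),
    `pato-size` = c("pato-increased_size", "pato-increased_thickness",
                    "pato-increased_height", "pato-decreased_magnitude"),
    `pato-texture` = c("pato-smooth", "pato-punctate"))
}

#' Generate a synthetic description with ground-truth tallies
#'
#' Draws statements from the eight phenotype families over the fixture
#' vocabulary. The returned tallies (focal individuals, individuals per
#' characteristic class, individuals per body region, measurement values)
#' are computed constructively while emitting each statement, independent
#' of compiler and reasoner, so they serve as oracles.
#'
#' @param seed integer seed; the same seed and counts give identical text.
#' @param counts named integer vector of statements per family (names:
#'   presence, absence, count_list, quality, measurement,
#'   relative_measurement, within_comparison, between_species, positional).
#' @param otu focal OTU id.
#' @param foreign_otu OTU referenced by between-species comparisons.
#' @return list with `text` (description source lines), `tallies` (list:
#'   `individuals` for the focal OTU, `foreign_individuals`, `by_class`,
#'   `by_region`, `values`) and `meta` (tags used, for mutant targeting).
#' @export
generate_description <- function(seed = 1L,
                                 counts = c(presence = 2L, absence = 1L,
                                            count_list = 1L, quality = 2L,
                                            measurement = 1L,
                                            relative_measurement = 1L,
                                            within_comparison = 1L,
                                            between_species = 1L,
                                            positional = 1L),
                                 otu = "grebennikovius_armiger",
                                 foreign_otu = "grebennikovius_basilewskyi") {
  set.seed(seed)
  ents <- synthetic_entity_pool()
  quals <- synthetic_quality_pool()
  if (sum(counts) > 0L && nrow(ents) == 0L) {
    stop("empty vocabulary pool", call. = FALSE)
  }

  text <- sprintf("OTU %s ;", otu)
  tally <- list(
    individuals = 1L,            # the focal organism individual
    foreign_individuals = 0L,
    by_class = c(`pato-colour` = 0L, `pato-shape` = 0L, `pato-size` = 0L,
                 `pato-texture` = 0L),
    by_region = c(head_or_part = 0L, thorax_or_part = 0L,
                  abdomen_or_part = 0L, leg_or_part = 0L),
    values = numeric(0))
  meta <- list(datum_tags = character(0), absence_tag = NA_character_,
               absence_denied = NA_character_)
  n_datum <- 0L
  n_anchor <- 0L

  pick_entity <- function() ents[sample.int(nrow(ents), 1L), ]
  add_region <- function(region, n = 1L) {
    tally$by_region[[region]] <<- tally$by_region[[region]] + as.integer(n)
  }
  add_class <- function(fam, n = 1L) {
    tally$by_class[[fam]] <<- tally$by_class[[fam]] + as.integer(n)
  }
  emit <- function(line) text <<- c(text, line)

  for (fam in names(counts)) {
    for (rep_i in seq_len(counts[[fam]])) {
      if (fam == "presence") {
        e <- pick_entity()
        emit(sprintf("uberon-male_organism > %s;", e$curie))
        tally$individuals <- tally$individuals + 1L
        add_region(e$region)
      } else if (fam == "absence") {
        # a tagged protibia denying a cuticular spine; the tag makes the
        # add-clashing-part mutant target exactly this individual
        first <- is.na(meta$absence_tag)
        meta$absence_tag <- "id-prot"
        meta$absence_denied <- "aism-cuticular_spine"
        emit("uberon-male_organism > aism-protibia:id-prot !> aism-cuticular_spine;")
        if (first) {
          tally$individuals <- tally$individuals + 1L
          add_region("leg_or_part")
        }
      } else if (fam == "count_list") {
        e <- pick_entity()
        emit(sprintf(
          "uberon-male_organism > %s > (aism-cuticular_tubercle, aism-cuticular_seta);",
          e$curie))
        tally$individuals <- tally$individuals + 3L
        add_region(e$region, 3L)
      } else if (fam == "quality") {
        e <- pick_entity()
        fams <- sample(names(quals), 2L)
        q1 <- sample(quals[[fams[1]]], 1L)
        q2 <- sample(quals[[fams[2]]], 1L)
        emit(sprintf("uberon-male_organism > %s >> (%s, %s);",
                     e$curie, q1, q2))
        tally$individuals <- tally$individuals + 3L
        add_region(e$region)
        add_class(fams[1]); add_class(fams[2])
      } else if (fam == "measurement") {
        n_datum <- n_datum + 1L
        tag <- sprintf("md-%03d", n_datum)
        meta$datum_tags <- c(meta$datum_tags, tag)
        val <- round(stats::runif(1, 1, 9), 1)
        emit(sprintf(paste0(
          "uberon-male_organism >> pato-length ",
          ".iao-is_quality_measured_as iao-measurement_datum:%s ",
          ".aism-has_unit unit-millimeter;"), tag))
        emit(sprintf("iao-measurement_datum:%s .iao-has_measurement_value %s;",
                     tag, format(val, trim = TRUE)))
        tally$individuals <- tally$individuals + 3L
        add_class("pato-size")
        tally$values <- c(tally$values, val)
      } else if (fam == "relative_measurement") {
        n_datum <- n_datum + 1L
        n_anchor <- n_anchor + 1L
        tag <- sprintf("md-%03d", n_datum)
        anchor <- sprintf("id-e%02d", n_anchor)
        meta$datum_tags <- c(meta$datum_tags, tag)
        e <- pick_entity()
        val <- round(stats::runif(1, 1, 3), 1)
        emit(sprintf(paste0(
          "uberon-male_organism > %s:%s >> aism-interpunctural_distance ",
          ".iao-is_quality_measured_as iao-measurement_datum:%s ",
          ".aism-has_unit pato-diameter ",
          "<< aism-ocellate_setigerous_cuticular_puncture < %s:%s;"),
          e$curie, anchor, tag, e$curie, anchor))
        emit(sprintf("iao-measurement_datum:%s .iao-has_measurement_value %s;",
                     tag, format(val, trim = TRUE)))
        # entity, distance quality, datum, diameter quality, puncture
        tally$individuals <- tally$individuals + 5L
        add_class("pato-size", 2L)      # interpunctural distance + diameter
        add_region(e$region, 2L)        # entity + puncture part of it
        tally$values <- c(tally$values, val)
      } else if (fam == "within_comparison") {
        pair <- ents[sample.int(nrow(ents), 2L), ]
        emit(sprintf(paste0(
          "uberon-male_organism > %s > aism-setigerous_cuticular_puncture ",
          ">> pato-diameter |<| pato-diameter ",
          "<< aism-setigerous_cuticular_puncture < %s;"),
          pair$curie[1], pair$curie[2]))
        tally$individuals <- tally$individuals + 6L
        add_class("pato-size", 2L)
        add_region(pair$region[1], 2L)
        add_region(pair$region[2], 2L)
      } else if (fam == "between_species") {
        emit(sprintf(paste0(
          "uberon-male_organism::%s > aism-hind_wing >> pato-length ",
          "|<| pato-length:id-fw%02d[exclude = True] ",
          "<< aism-hind_wing:id-fh%02d[exclude = True] ",
          "< uberon-male_organism:%s[exclude = True];"),
          otu, rep_i, rep_i, foreign_otu))
        tally$individuals <- tally$individuals + 2L
        tally$foreign_individuals <- tally$foreign_individuals + 2L
        add_class("pato-size")
        add_region("thorax_or_part")
      } else if (fam == "positional") {
        n_anchor <- n_anchor + 1L
        anchor <- sprintf("id-e%02d", n_anchor)
        emit(sprintf(paste0(
          "uberon-male_organism > colao-elytron_with_9_striae:%s > ",
          "colao-elytral_interstria_8 > aism-cuticular_carina ",
          ".aism-medial_to bspo-lateral_region < colao-elytron_with_9_striae:%s;"),
          anchor, anchor))
        tally$individuals <- tally$individuals + 4L
        add_region("thorax_or_part", 4L)
      }
    }
  }
  list(text = text, tallies = tally, meta = meta)
}

#' Apply a named defect to a generated description
#'
#' Each mutant differs from the clean text by exactly one defect:
#' `drop-datum-value` removes one measurement-value line (validator
#' minCount violation); `drop-species-link` appends a statement whose
#' individuals never connect to an organism (species-linkage violation);
#' `add-clashing-part` asserts the part whose absence the description
#' states (reasoner clash); `duplicate-tag-conflict` reuses a datum tag
#' with a different class (compile error).
#'
#' @param gen output of [generate_description()].
#' @param kind mutation kind (or `"none"`).
#' @return Mutated description text lines.
#' @export
mutate_description <- function(gen, kind = c("none", "drop-datum-value",
                                             "drop-species-link",
                                             "add-clashing-part",
                                             "duplicate-tag-conflict")) {
  kind <- match.arg(kind)
  text <- gen$text
  if (kind == "none") return(text)
  if (kind == "drop-datum-value") {
    if (length(gen$meta$datum_tags) == 0L) {
      stop("no measurement statement to mutate", call. = FALSE)
    }
    tag <- gen$meta$datum_tags[1]
    hit <- grep(sprintf("^iao-measurement_datum:%s \\.iao-has_measurement_value",
                        tag), text)
    return(text[-hit[1]])
  }
  if (kind == "drop-species-link") {
    return(c(text, "aism-cuticular_seta:id-orphan >> pato-smooth;"))
  }
  if (kind == "add-clashing-part") {
    if (is.na(gen$meta$absence_tag)) {
      stop("no absence statement to mutate", call. = FALSE)
    }
    return(c(text, sprintf("uberon-male_organism > aism-protibia:%s > %s;",
                           gen$meta$absence_tag, gen$meta$absence_denied)))
  }
  # duplicate-tag-conflict
  if (length(gen$meta$datum_tags) == 0L) {
    stop("no tagged statement to mutate", call. = FALSE)
  }
  c(text, sprintf("pato-length:%s .iao-has_measurement_value 3;",
                  gen$meta$datum_tags[1]))
}

#' Paths of the golden re-encoded taxon treatments
#'
#' Four hand re-encoded description sources whose generated NL follows the
#' published treatments of the *Grebennikovius* species. Derived from the
#' printed natural-language descriptions (not from supplementary files),
#' so divergences in encoding conventions are possible and are documented
#' in the package vignette.
#'
#' @return Named character vector of `.phs` file paths.
#' @export
golden_treatments <- function() {
  dir <- system.file("extdata", "goldens", package = "phenoscribe")
  if (dir == "") dir <- file.path("inst", "extdata", "goldens")
  files <- list.files(dir, pattern = "\\.phs$", full.names = TRUE)
  stats::setNames(files, sub("\\.phs$", "", basename(files)))
}

#' Path of the bundled fixture project configuration
#' @return File path of the YAML configuration for the golden treatments.
#' @export
fixture_config_path <- function() {
  p <- system.file("extdata", "fixture_config.yaml", package = "phenoscribe")
  if (p == "") p <- file.path("inst", "extdata", "fixture_config.yaml")
  p
}
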