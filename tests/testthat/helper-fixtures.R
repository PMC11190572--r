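# Shared fixtures: the bundled mini-ontology and project configuration are
# loaded once per test run.

fixture_tbox <- local({
  tb <- NULL
  function() {
    if (is.null(tb)) tb <<- build_fixture_ontology()
    tb
  }
})

fixture_config <- function() fixture_config_path()

# the printed pattern statements, one per syntactic family
pattern_statements <- function() c(
  "uberon-male_organism > aism-metafemur > bspo-dorsal_margin > aism-cuticular_carina;",
  "uberon-male_organism > colao-elytral_interstria_5 > bspo-distal_region > aism-cuticular_tubercle;",
  "uberon-male_organism > colao-fused_axial_and_subaxial_endophallites;",
  "uberon-male_organism !> colao-posterior_longitudinal_hypomeral_carina;",
  "uberon-male_organism > aism-protibia !> aism-dorsal_protibial_cuticular_tooth_4;",
  "uberon-male_organism > aism-maxillary_palpus_with_4_palpomeres;",
  "uberon-male_organism > (aism-protarsus_with_5_protarsomeres, aism-mesotarsus_with_5_mesotarsomeres, aism-metatarsus_with_5_metatarsomeres);",
  "uberon-male_organism > aism-protibia > (aism-dorsal_protibial_cuticular_tooth_1, aism-dorsal_protibial_cuticular_tooth_2, aism-dorsal_protibial_cuticular_tooth_3);",
  "uberon-male_organism >> (pato-ovate, pato-flattened);",
  "uberon-male_organism > aism-lateral_clypeal_tooth_1 >> (pato-upturned, pato-sharp);",
  "uberon-male_organism > aism-vertex > bspo-posterior_region > bspo-medial_region >> pato-smooth;",
  "uberon-male_organism > aism-pronotum > bspo-posterior_region > aism-row_of_punctures > aism-ocellate_cuticular_puncture >> (pato-increased_size, pato-ovate);",
  "uberon-male_organism > colao-scutellar_shield >> pato-concealed;",
  "uberon-male_organism > colao-mesometaventral_sulcus > bspo-medial_region >> pato-curved;",
  "uberon-male_organism > aism-metatibia > bspo-distal_region >> pato-dilated;",
  "uberon-male_organism > aism-protibia > aism-antero-distal_margin > aism-cuticular_seta >> (pato-multiple, pato-increased_thickness);",
  "uberon-male_organism > aism-parameres >> (pato-symmetrical, pato-elongated);",
  "uberon-male_organism >> pato-length .iao-is_quality_measured_as iao-measurement_datum:md-c4c164 .aism-has_unit unit-millimeter;",
  "iao-measurement_datum:md-c4c164 .iao-has_measurement_value 4.5;",
  "uberon-male_organism > aism-pronotum:id-1549f8 >> aism-interpunctural_distance .iao-is_quality_measured_as iao-measurement_datum:md-1b36aa .aism-has_unit pato-diameter << aism-ocellate_setigerous_cuticular_puncture < aism-pronotum:id-1549f8;",
  "iao-measurement_datum:md-1b36aa .iao-has_measurement_value 1.5;",
  "uberon-male_organism > aism-clypeus > bspo-anterior_region > aism-setigerous_cuticular_puncture >> pato-diameter |<| pato-diameter << aism-setigerous_cuticular_puncture < aism-frons;",
  "uberon-male_organism > aism-left_ventral_conjunctiva_of_paramere >> pato-thickness .ro-similar_in_magnitude_relative_to pato-thickness << aism-right_ventral_conjunctiva_of_paramere < uberon-male_organism;",
  "uberon-male_organism::grebennikovius_armiger > aism-hind_wing >> pato-length |<| pato-length:id-d38816[exclude = True] << aism-hind_wing:id-6b490e[exclude = True] < uberon-male_organism:grebennikovius_basilewskyi[exclude = True];",
  "uberon-male_organism > colao-elytron_with_9_striae:id-5770f5 > colao-elytral_interstria_8 > aism-cuticular_carina .aism-medial_to bspo-lateral_region < colao-elytron_with_9_striae:id-5770f5;",
  "uberon-male_organism > aism-abdominal_tergite_VIII:id-791f84 > bspo-anatomical_margin .ro-coincident_with aism-cuticular_groove < aism-abdominal_tergite_VIII:id-791f84;"
)

pattern_document <- function() {
  c("OTU grebennikovius_armiger ;", pattern_statements())
}

compile_pattern_document <- function() {
  doc <- parse_document(pattern_document(), fixture_config())
  compile_abox(doc, fixture_tbox())
}
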