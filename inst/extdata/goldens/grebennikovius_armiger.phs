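# Golden re-encoding of the published Grebennikovius armiger treatment,
# derived from the printed natural-language description.
OTU grebennikovius_armiger ;

uberon-male_organism > uberon-chitin-based_cuticle >> pato-red_brown;
uberon-male_organism > bspo-ventral_side >> pato-dark_brown;
uberon-male_organism > aism-antenna >> pato-yellow_brown;
uberon-male_organism > aism-gena >> pato-sharp;
uberon-male_organism > aism-lateral_clypeal_tooth_1 >> (pato-upturned, pato-sharp);
uberon-male_organism > aism-head_margin_at_genoclypeal_sulcus >> pato-notched;
uberon-male_organism > aism-head_capsule > aism-frons >> aism-interpunctural_distance .iao-is_quality_measured_as iao-measurement_datum:md-a01 .aism-has_unit pato-diameter << aism-setigerous_cuticular_puncture;
iao-measurement_datum:md-a01 .iao-has_measurement_value 1.0;
uberon-male_organism > aism-clypeus > bspo-anterior_region > aism-setigerous_cuticular_puncture >> pato-diameter |<| pato-diameter << aism-setigerous_cuticular_puncture < aism-frons;
uberon-male_organism > aism-vertex > bspo-posterior_region > bspo-medial_region >> pato-smooth;
uberon-male_organism > aism-antenna_with_9_antennomeres > aism-antennal_club > (aism-flagellomere_5, aism-flagellomere_6, aism-flagellomere_7);
uberon-male_organism > aism-glossa;
uberon-male_organism > aism-epipharynx;
uberon-male_organism > aism-insect_maxilla;
uberon-male_organism > aism-maxillary_palpus_with_4_palpomeres;
uberon-male_organism > aism-labial_palpus_with_3_palpomeres;
uberon-male_organism > aism-pronotum:id-pn > bspo-antero-lateral_region >> pato-flattened;
uberon-male_organism > aism-pronotum:id-pn > bspo-posterior_region:id-ppr > aism-row_of_punctures > aism-ocellate_cuticular_puncture >> (pato-increased_size, pato-ovate);
bspo-posterior_region:id-ppr >> pato-sloped;
uberon-male_organism > aism-pronotum:id-pn > bspo-antero-lateral_margin >> (pato-curved, pato-obtuse);
uberon-male_organism > aism-pronotum:id-pn > colao-posterolateral_pronotal_angle >> pato-curved;
uberon-male_organism > aism-pronotum:id-pn > bspo-posterior_margin >> pato-curved;
uberon-male_organism > aism-pronotum:id-pn > bspo-postero-lateral_margin >> pato-oblique_orientation;
uberon-male_organism > aism-pronotum:id-pn > colao-longitudinal_pronotal_groove >> pato-smooth;
uberon-male_organism > aism-pronotum:id-pn >> pato-width |>| pato-width << colao-elytron_with_9_striae:id-el < uberon-male_organism;
colao-elytron_with_9_striae:id-el > colao-elytral_stria:id-st > aism-cuticular_puncture >> pato-diameter .iao-is_quality_measured_as iao-measurement_datum:md-a02 .aism-has_unit pato-width << colao-elytral_stria:id-st;
iao-measurement_datum:md-a02 .iao-has_measurement_value 3;
colao-elytron_with_9_striae:id-el > colao-elytral_interstria_8 > aism-cuticular_carina:id-ca .aism-medial_to bspo-lateral_region:id-lr < colao-elytron_with_9_striae:id-el;
bspo-lateral_region:id-lr >> pato-sloped;
aism-cuticular_carina:id-ca > bspo-distal_region >> pato-increased_height;
uberon-male_organism > aism-pronotum:id-pn >> aism-interpunctural_distance .iao-is_quality_measured_as iao-measurement_datum:md-a03 .aism-has_unit pato-diameter << aism-ocellate_setigerous_cuticular_puncture < aism-pronotum:id-pn;
iao-measurement_datum:md-a03 .iao-has_measurement_value 1.5;
uberon-male_organism > colao-pronotal_disc >> pato-convex;
uberon-male_organism > colao-elytral_interstria_5:id-i5 > bspo-proximal_region >> pato-concave;
colao-elytral_interstria_5:id-i5 !> aism-cuticular_tubercle;
uberon-male_organism > colao-elytral_interstria_6 > bspo-anterior-most_region >> pato-concave;
uberon-male_organism > colao-scutellar_shield >> pato-concealed;
uberon-male_organism > aism-hind_wing:id-hw >> pato-atrophied;
aism-hind_wing:id-hw >> pato-length |<| pato-length:id-fal[exclude = True] << aism-hind_wing:id-fah[exclude = True] < uberon-male_organism:grebennikovius_basilewskyi[exclude = True];
uberon-male_organism > colao-anterior_hypomeral_depression;
uberon-male_organism > aism-procoxal_cavity >> pato-width .iao-is_quality_measured_as iao-measurement_datum:md-a04 .aism-has_unit pato-width << aism-pronotum:id-pn;
iao-measurement_datum:md-a04 .iao-has_measurement_value 0.375;
uberon-male_organism > colao-mesometaventral_sulcus:id-ms > bspo-medial_region >> pato-curved;
colao-mesometaventral_sulcus:id-ms > bspo-lateral_region >> pato-straight;
uberon-male_organism > aism-mesoventrite > aism-cuticular_puncture;
uberon-male_organism > aism-metaventrite:id-mv > aism-punctate_cuticle:id-pc > bspo-posterior_region > aism-cuticular_puncture >> pato-diameter |<| pato-diameter << aism-cuticular_puncture < bspo-anterior_region < aism-punctate_cuticle:id-pc;
aism-punctate_cuticle:id-pc >> aism-interpunctural_distance .iao-is_quality_measured_as iao-measurement_datum:md-a05 .aism-has_unit pato-diameter << aism-cuticular_puncture;
iao-measurement_datum:md-a05 .iao-has_measurement_value 1.5;
aism-metaventrite:id-mv >> pato-convex;
uberon-male_organism > colao-abdomen_with_7_sternites;
uberon-male_organism > aism-abdominal_tergite_VIII:id-t8 > bspo-anatomical_margin .ro-coincident_with aism-cuticular_groove < aism-abdominal_tergite_VIII:id-t8;
aism-abdominal_tergite_VIII:id-t8 > aism-cuticle_with_setigerous_punctures > aism-ocellate_setigerous_cuticular_puncture;
aism-abdominal_tergite_VIII:id-t8 > aism-cuticular_tubercle >> pato-bilaterally_paired;
uberon-male_organism > colao-anterior_groove_of_tergite_VIII;
uberon-male_organism > aism-protarsus_with_5_protarsomeres;
uberon-male_organism > aism-mesotarsus_with_5_mesotarsomeres;
uberon-male_organism > aism-metatarsus_with_5_metatarsomeres;
uberon-male_organism > aism-protibia:id-pt > (aism-dorsal_protibial_cuticular_tooth_1, aism-dorsal_protibial_cuticular_tooth_2, aism-dorsal_protibial_cuticular_tooth_3);
aism-protibia:id-pt > aism-antero-distal_margin > aism-cuticular_seta >> (pato-multiple, pato-increased_thickness);
aism-protibia:id-pt > aism-postero-distal_margin >> (pato-dilated, pato-curved);
aism-protibia:id-pt >> pato-curved;
aism-protibia:id-pt !> aism-dorsal_protibial_cuticular_tooth_4;
uberon-male_organism > aism-mesotibia > bspo-distal_region >> pato-dilated;
uberon-male_organism > aism-metatibia:id-mt > bspo-distal_region >> pato-dilated;
aism-metatibia:id-mt > bspo-medial_region >> pato-curved;
aism-metatibia:id-mt > bspo-dorsal_margin > bspo-distal_region >> pato-curved;
uberon-male_organism > aism-profemur > bspo-ventral_side >> (pato-dilated, pato-tapered);
uberon-male_organism > aism-metafemur:id-mf > bspo-dorsal_margin > aism-cuticular_carina;
aism-metafemur:id-mf > bspo-ventral_margin > aism-cuticular_protrusion >> (pato-triangular, pato-flattened);
uberon-male_organism > aism-procoxa > bspo-ventral_region > aism-cuticular_carina > aism-cuticular_tubercle;
uberon-male_organism > aism-parameres:id-pa > bspo-ventral_side > bspo-proximal_region >> pato-notched;
aism-parameres:id-pa > bspo-lateral_side > bspo-distal_region >> pato-tapered;
aism-parameres:id-pa >> (pato-symmetrical, pato-elongated);
uberon-male_organism > aism-left_ventral_conjunctiva_of_paramere >> pato-thickness .ro-similar_in_magnitude_relative_to pato-thickness << aism-right_ventral_conjunctiva_of_paramere < uberon-male_organism;
uberon-male_organism > colao-lamella_copulatrix >> (pato-elongated, pato-straight);
uberon-male_organism > colao-fused_axial_and_subaxial_endophallites;
uberon-male_organism >> (pato-ovate, pato-flattened);
uberon-male_organism !> colao-posterior_longitudinal_hypomeral_carina;
uberon-male_organism !> colao-frontolateral_peripheral_endophallite;
uberon-male_organism >> pato-length .iao-is_quality_measured_as iao-measurement_datum:md-a06 .aism-has_unit unit-millimeter;
iao-measurement_datum:md-a06 .iao-has_measurement_value 4.5;
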