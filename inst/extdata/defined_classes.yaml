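# Defined body-region classes "X or (part_of some X)" used by the region
# count queries. Names map to the base-class curie.
head_or_part: aism-insect_head
thorax_or_part: aism-insect_thorax
abdomen_or_part: aism-insect_abdomen
leg_or_part: aism-insect_leg
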