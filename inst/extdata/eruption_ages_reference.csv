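position,tooth,maxillary_eruption_years,mandibular_eruption_years
1,central_incisor,7.3,6.3
2,lateral_incisor,8.3,7.5
3,canine,11.5,10.5
4,first_premolar,10.3,10.6
5,second_premolar,11.0,11.3
6,first_molar,6.3,6.1
7,second_molar,12.4,11.9
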