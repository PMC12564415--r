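id,group,sex,dur_egg,dur_larva,dur_adult,death_stage
A,TOY,F,2,2,2,adult
B,TOY,U,2,,,larva
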