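compound_id	category
c1	excluded_known
c2	anticancer
c3	anticancer
c4	novel
c5	nonhit
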