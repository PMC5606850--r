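# Tail/core residue selections per species, E. coli numbering throughout.
# core:        Sm core residues (range string or integer list)
# basic_core:  arginine/lysine-rich rim + NTD residues used for the EEC sum
# tail:        acidic C-terminal tip residues
numbering_scheme: "E. coli"
species:
  "E. coli":
    core: "1-65"
    basic_core: [3, 16, 17, 19, 47]
    tail: [97, 99, 100, 102]
  "P. aeruginosa":
    core: "1-65"
    basic_core: [3, 5, 16, 17, 19, 47]
    tail: [94, 97]
  "L. monocytogenes":
    core: "1-65"
    basic_core: [2, 16, 17, 19, 35]
    tail: [100, 102]
  "B. subtilis":
    core: "1-65"
    basic_core: [2, 16, 17, 37]
    tail: [100, 102]
  "S. aureus":
    # residue 65 opens the acidic tail here, so the core role stops at 64
    core: "1-64"
    basic_core: [10, 16, 41]
    tail: [65, 67, 99, 101, 102]
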