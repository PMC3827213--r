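# Shared constants (this file sorts first in the collate order).

# The 20 standard amino acids; X is the only ambiguity code carried through.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
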