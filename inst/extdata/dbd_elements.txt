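a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 a1 - - - - b1 b1 b1 b1 b1 - b2 b2 b2 b2 b2 - - a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 a2 - - - a3 a3 a3 a3 a3 a3 a3 a3 a3 a3 a3 a3 a3 - - b3 b3 b3 b3 - - - b4 b4 b4 b4 - - - - - - - - - -
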