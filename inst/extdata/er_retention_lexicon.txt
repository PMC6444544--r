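AEKL
AQKM
DRVL
SAQK
SAEK
EQLK
GNMK
SHRM
ERCG
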