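# atom_class  map_type
CAL        APOLAR
CHC        GEHC
NDA        HBDON
OAC        HBACC
NPO        MAMN
CCX        ACEC
OHX        MEOO
CAM        FORC
SUL        unmapped
HX         unmapped
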