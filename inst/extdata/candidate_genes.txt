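CD44
GADD45B
STAT3
GFAP
CDC42EP2
CDC42
ALOX15B
AGEC08
AGEC09
AGEC10
AGEC11
AGEC12
AGEC13
AGEC14
AGEC15
AGEC16
AGEC17
AGEC18
AGEC19
AGEC20
AGEC21
AGEC22
AGEC23
AGEC24
AGEC25
AGEC26
AGEC27
AGEC28
AGEC29
AGEC30
AGEC31
AGEC32
AGEC33
AGEC34
AGEC35
AGEC36
AGEC37
AGEC38
AGEC39
AGEC40
AGEC41
AGEC42
AGEC43
AGEC44
AGEC45
AGEC46
AGEC47
AGEC48
AGEC49
AGEC50
AGEC51
AGEC52
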