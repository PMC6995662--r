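SG0010
SG0200
SG0400
SG0600
SG0800
SG1000
SG1200
SG1400
SG1600
SG1800
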