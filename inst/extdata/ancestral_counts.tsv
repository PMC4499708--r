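node	description	count
V	Viridiplantae MRCA	7
E	Embryophyte MRCA	32
T	Tracheophyte MRCA	44
Eu	eudicot MRCA	109
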