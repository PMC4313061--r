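# subdomain partition: name: monomer start-end[, ...]  (see ?read_partition)
TM:  A 1-56,    B 1-56,    C 1-56
PN1: A 57-112,  B 57-112,  C 57-112
PN2: A 113-168, B 113-168, C 113-168
PC1: A 169-224, B 169-224, C 169-224
PC2: A 225-280, B 225-280, C 225-280
DN:  A 281-336, B 281-336, C 281-336
DC:  A 337-392, B 337-392, C 337-392
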