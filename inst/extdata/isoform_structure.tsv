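isoform	absent_canonical
2N4R	
0N4R	45-102
mouse	45-55
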