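# central-ring positions forbidden to pair (0-based; half-open ranges)
12-16
28-32
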