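>Tsyn synthetic-stand-in intrinsic terminator (constructed GC stem-loop plus U-tract; not a natural terminator sequence)
GGCACCGGATCCTTATAGGATCCGGTGCCTTTTTTTT
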