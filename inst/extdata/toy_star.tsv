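# 3-node star: hub drives two leaves
hub leaf1
hub leaf2
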