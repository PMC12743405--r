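{"ts":"2026-09-11T13:56:10","event":"start","mode":"coords","seed":1}
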