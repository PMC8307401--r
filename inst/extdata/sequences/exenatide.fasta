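>exenatide exendin-4, single chain
HGEGTFTSDLSKQMEEEAVRLFIEWLKNGGPSSGAPPPS
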