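# Parameter set of the packaged delay/amplitude-sweep reproduction:
# nominal values plus a working neural-control amplitude on the stable
# negative branch (see the methods vignette for how it was chosen).
r0: -0.2
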