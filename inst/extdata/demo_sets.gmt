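demo_clock	na	P000001	P000002	P000003	P000004
demo_mqtl	na	P000001	P000002	P000003	P000012	P000005
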