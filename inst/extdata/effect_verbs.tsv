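verb	effect
increase	increase
increases	increase
overexpress	increase
overexpresses	increase
overexpression	increase
elevate	increase
elevates	increase
upregulate	increase
upregulates	increase
upregulation	increase
induce	increase
induces	increase
decrease	decrease
decreases	decrease
inhibit	decrease
inhibits	decrease
silence	decrease
silences	decrease
suppress	decrease
suppresses	decrease
reduce	decrease
reduces	decrease
downregulate	decrease
downregulates	decrease
downregulation	decrease
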