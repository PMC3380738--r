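# Two overlapping clusters whose best f-measure match is the Set3p complex
cluster-1 : YGL194C YKR029C YCR033W YIL112W
cluster-2 : YGL194C YKR029C YBR103W
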