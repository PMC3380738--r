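# Three overlapping clusters whose best f-measure match is the
# Prp19-associated complex
cluster-1 : YLL036C YDR416W YMR213W YGR129W YLR117C YNR011C YDR364C
cluster-2 : YLL036C YJR050W YDR416W YGR129W YLR117C YPL213W YIR009W
cluster-3 : YLL036C YDR416W YBR188C YGR129W YLR117C YPR101W
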