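# Example gold-standard complexes (S. cerevisiae, systematic ORF names)
Prp19-associated : YLL036C YMR213W YJR050W YLR117C YDR416W YGR129W YBR188C YPR101W
Set3p : YGL194C YIL112W YDR155C YOL068C YKR029C YBR103W YCR033W
cAMP-dependent-PK : YIL033C YJL164C YPL203W YKL166C
NuA4-HAT : YFL039C YJL081C YPR023C YEL018W YJR082C YNL136W YFL024C YOR244W YGR002C YHR099W YDR359C YNL107W YHR090C
RAVE : YJR033C YDR202C YDR328C
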