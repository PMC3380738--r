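# Overlapping preliminary clusters for the five example complexes
prp19-1 : YLL036C YDR416W YMR213W YGR129W YLR117C YNR011C YDR364C
prp19-2 : YLL036C YJR050W YDR416W YGR129W YLR117C YPL213W YIR009W
prp19-3 : YLL036C YDR416W YBR188C YGR129W YLR117C YPR101W
set3p-1 : YGL194C YKR029C YCR033W YIL112W
set3p-2 : YGL194C YKR029C YBR103W
camp-1 : YNL227C YKL166C YPL203W
camp-2 : YIL033C YPL203W
nua4-1 : YNL107W YOR244W YFL024C YPR023C
nua4-2 : YJL081C YFL024C
rave-1 : YDR306C YDR202C YJL204C YGL149W YOR080W YJL149W YMR258C YBR280C YJR033C YML088W YDR131C YLR368W YLR097C YDL132W YLR352W YDR328C YLR224W
rave-2 : YMR054W YJR033C YDR202C YOR270C YBR127C YDL185W YHR060W
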