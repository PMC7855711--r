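lncrna_id	role
DLEU1	tumor_suppressor
LINC00261	tumor_suppressor
LINC00483	tumor_suppressor
LINC01207	tumor_suppressor
MCF2L-AS1	tumor_suppressor
MEG3	oncogene
RUNX1-IT1	oncogene
TP73-AS1	oncogene
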