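feature_id	direction
CYP1B1	up
NPR3	up
RGL2	up
SLIT2	up
TSPAN2	up
ACOT7	down
AGPAT5	down
ATP5B	down
AURKAIP1	down
CASP1	down
CEP55	down
CXCL3	down
FUT4	down
GSR	down
HNRNPAB	down
IDO1	down
KIF11	down
MCM5	down
PBK	down
PIGR	down
RANBP1	down
SCO2	down
TOE1	down
TTLL12	down
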