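electrode	DAN	DMN	FPN	LN	SMN	SN	VAN	VN
Fp1	0	0.6	0.25	0	0	0.15	0	0
Fp2	0	0.6	0.25	0	0	0.15	0	0
AF3	0	0.6	0.25	0	0	0.15	0	0
AF4	0	0.6	0.25	0	0	0.15	0	0
TP7	0	0.6	0.25	0	0	0.15	0	0
TP8	0	0.6	0.25	0	0	0.15	0	0
Fz	0	0.15	0.25	0	0	0.6	0	0
F1	0	0.15	0.25	0	0	0.6	0	0
F2	0	0.15	0.25	0	0	0.6	0	0
FC1	0	0.15	0.25	0	0	0.6	0	0
FC2	0	0.15	0.25	0	0	0.6	0	0
F3	0.15	0.25	0.6	0	0	0	0	0
F4	0.15	0.25	0.6	0	0	0	0	0
F5	0.15	0.25	0.6	0	0	0	0	0
F6	0.15	0.25	0.6	0	0	0	0	0
FC3	0.15	0.25	0.6	0	0	0	0	0
FC4	0.15	0.25	0.6	0	0	0	0	0
P3	0.15	0.25	0.6	0	0	0	0	0
P4	0.15	0.25	0.6	0	0	0	0	0
AF7	0.15	0.25	0.6	0	0	0	0	0
AF8	0.15	0.25	0.6	0	0	0	0	0
F7	0	0	0.15	0	0	0.25	0.6	0
F8	0	0	0.15	0	0	0.25	0.6	0
FT7	0	0	0.15	0	0	0.25	0.6	0
FT8	0	0	0.15	0	0	0.25	0.6	0
T7	0	0	0.15	0	0	0.25	0.6	0
T8	0	0	0.15	0	0	0.25	0.6	0
FT9	0	0.15	0	0.6	0	0	0.25	0
FT10	0	0.15	0	0.6	0	0	0.25	0
TP9	0	0.15	0	0.6	0	0	0.25	0
TP10	0	0.15	0	0.6	0	0	0.25	0
PO9	0	0.15	0	0.6	0	0	0.25	0
PO10	0	0.15	0	0.6	0	0	0.25	0
C3	0.25	0	0	0	0.6	0	0.15	0
C4	0.25	0	0	0	0.6	0	0.15	0
C5	0.25	0	0	0	0.6	0	0.15	0
C6	0.25	0	0	0	0.6	0	0.15	0
Cz	0.25	0	0	0	0.6	0	0.15	0
C1	0.25	0	0	0	0.6	0	0.15	0
C2	0.25	0	0	0	0.6	0	0.15	0
FC5	0.25	0	0	0	0.6	0	0.15	0
FC6	0.25	0	0	0	0.6	0	0.15	0
CP1	0.25	0	0	0	0.6	0	0.15	0
CP2	0.25	0	0	0	0.6	0	0.15	0
CP3	0.25	0	0	0	0.6	0	0.15	0
CP4	0.25	0	0	0	0.6	0	0.15	0
CP5	0.25	0	0	0	0.6	0	0.15	0
CP6	0.25	0	0	0	0.6	0	0.15	0
CPz	0.25	0	0	0	0.6	0	0.15	0
Pz	0.6	0	0.25	0	0	0	0	0.15
P1	0.6	0	0.25	0	0	0	0	0.15
P2	0.6	0	0.25	0	0	0	0	0.15
P5	0.6	0	0.25	0	0	0	0	0.15
P6	0.6	0	0.25	0	0	0	0	0.15
P7	0.6	0	0.25	0	0	0	0	0.15
P8	0.6	0	0.25	0	0	0	0	0.15
O1	0.25	0	0	0.15	0	0	0	0.6
O2	0.25	0	0	0.15	0	0	0	0.6
Oz	0.25	0	0	0.15	0	0	0	0.6
PO3	0.25	0	0	0.15	0	0	0	0.6
PO4	0.25	0	0	0.15	0	0	0	0.6
PO7	0.25	0	0	0.15	0	0	0	0.6
PO8	0.25	0	0	0.15	0	0	0	0.6
POz	0.25	0	0	0.15	0	0	0	0.6
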