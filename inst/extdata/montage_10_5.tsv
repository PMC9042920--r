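name	x	y	z
Fp1	-25.716	79.144	27.039
Fp2	25.716	79.144	27.039
AF3	-25.751	72.709	41.31
AF7	-48.914	67.324	27.039
AF4	25.751	72.709	41.31
AF8	48.914	67.324	27.039
Fz	0	51.431	70.789
F1	-19.497	55.524	64.755
F3	-37.89	56.474	55.057
F5	-54.139	54.228	42.243
F7	-67.324	48.914	27.039
F2	19.497	55.524	64.755
F4	37.89	56.474	55.057
F6	54.139	54.228	42.243
F8	67.324	48.914	27.039
FC1	-24.845	30.686	78.085
FC3	-47.558	31.7	66.254
FC5	-66.191	29.995	48.737
FT7	-79.144	25.716	27.039
FC2	24.845	30.686	78.085
FC4	47.558	31.7	66.254
FC6	66.191	29.995	48.737
FT8	79.144	25.716	27.039
Cz	0	0	87.5
C1	-27.039	0	83.217
C3	-51.431	0	70.789
C5	-70.789	0	51.431
T7	-83.217	0	27.039
C2	27.039	0	83.217
C4	51.431	0	70.789
C6	70.789	0	51.431
T8	83.217	0	27.039
CPz	0	-27.039	83.217
CP1	-24.845	-30.686	78.085
CP3	-47.558	-31.7	66.254
CP5	-66.191	-29.995	48.737
TP7	-79.144	-25.716	27.039
CP2	24.845	-30.686	78.085
CP4	47.558	-31.7	66.254
CP6	66.191	-29.995	48.737
TP8	79.144	-25.716	27.039
Pz	0	-51.431	70.789
P1	-19.497	-55.524	64.755
P3	-37.89	-56.474	55.057
P5	-54.139	-54.228	42.243
P7	-67.324	-48.914	27.039
P2	19.497	-55.524	64.755
P4	37.89	-56.474	55.057
P6	54.139	-54.228	42.243
P8	67.324	-48.914	27.039
PO3	-25.751	-72.709	41.31
PO7	-48.914	-67.324	27.039
PO4	25.751	-72.709	41.31
PO8	48.914	-67.324	27.039
Oz	0	-83.217	27.039
O1	-25.716	-79.144	27.039
O2	25.716	-79.144	27.039
FT9	-83.217	27.039	0
TP9	-83.217	-27.039	0
PO9	-51.431	-70.789	0
FT10	83.217	27.039	0
TP10	83.217	-27.039	0
PO10	51.431	-70.789	0
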