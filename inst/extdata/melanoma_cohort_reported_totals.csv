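patient_id,reported_total
SV001,8
MS002,5
IM003,8
HV004,10
CV005,5
RI006,9
PC007,6
BN008,4
MR009,5
MI010,9
PS011,5
AM012,6
GN013,10
CM014,10
CN015,7
GU016,5
SM017,8
MS018,9
VS019,10
LV020,6
PD021,7
PG022,5
TV023,10
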