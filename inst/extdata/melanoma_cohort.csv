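patient_id,p16_pct,cd8_pct,ki67_pct,cdkn2a,split
SV001,50,0,40,disomy,test
MS002,50,20,20,heterozygous_deletion,test
IM003,50,0,25,heterozygous_deletion,test
HV004,0,0,40,homozygous_deletion,test
CV005,50,20,60,heterozygous_deletion,test
RI006,0,5,60,homozygous_deletion,test
PC007,50,0,10,disomy,test
BN008,50,20,10,monosomy,test
MR009,50,70,60,monosomy,test
MI010,0,5,60,homozygous_deletion,validation
PS011,50,10,10,disomy,test
AM012,50,40,70,disomy,validation
GN013,0,0,40,homozygous_deletion,validation
CM014,0,0,50,homozygous_deletion,validation
CN015,50,5,50,disomy,validation
GU016,50,10,10,disomy,validation
SM017,50,0,60,monosomy,test
MS018,0,0,20,homozygous_deletion,validation
VS019,0,0,80,monosomy,validation
LV020,0,90,20,monosomy,validation
PD021,50,5,30,disomy,validation
PG022,50,5,10,monosomy,validation
TV023,0,0,50,homozygous_deletion,validation
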