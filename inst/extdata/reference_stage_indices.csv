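stage,index,mean,sem
awake,hr_bpm,60,0.4
awake,lf_ms2,824,10
awake,hf_ms2,234,5
awake,sp_mmHg,111,1
awake,dp_mmHg,75,1
awake,lambda0,0.019,0.001
rem,hr_bpm,59,0.3
rem,lf_ms2,249,7
rem,hf_ms2,224,4
rem,sp_mmHg,110,1
rem,dp_mmHg,74,1
rem,lambda0,0.022,0.001
nrem,hr_bpm,57,0.3
nrem,lf_ms2,208,5
nrem,hf_ms2,279,3
nrem,sp_mmHg,105,1
nrem,dp_mmHg,68,1
nrem,lambda0,0.022,0.001
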