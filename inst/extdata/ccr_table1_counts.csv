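group,tp,fp,fn,tn
platinum_doublet,2442,90,246,14532
pemetrexed_based,1974,159,140,15037
bevacizumab_based,467,35,63,16745
pem_bev,618,114,17,16561
single_agent,288,189,37,16796
tki,1599,287,117,15307
no_treatment,4844,895,642,10929
unknown,2836,473,981,13020
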