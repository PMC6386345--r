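canonical,drug_class,variants,match_as_word
cisplatin,platinum,cddp|platinol|cisplatnum|cisplastin,true
carboplatin,platinum,carbo|paraplatin|carboplatnum|carboplatin aq,true
pemetrexed,pemetrexed,alimta|premetrexed|pemetrexed disodium|pemextred,true
bevacizumab,bevacizumab,avastin|bevacuzimab|bevacizamab,true
erlotinib,tki,tarceva|erlotnib|erlotinab,true
gefitinib,tki,iressa|gefitnib,true
afatinib,tki,gilotrif|afatnib,true
crizotinib,tki,xalkori|crizotnib,true
paclitaxel,other_chemo,taxol|paclitaxol|paclitax,true
nab-paclitaxel,other_chemo,abraxane|nab paclitaxel,true
docetaxel,other_chemo,taxotere|docetaxol,true
gemcitabine,other_chemo,gemzar|gemcitabene|gemcitibine,true
vinorelbine,other_chemo,navelbine|vinorelbin,true
etoposide,other_chemo,vp-16|vepesid|etopside,true
irinotecan,other_chemo,camptosar|cpt-11,true
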