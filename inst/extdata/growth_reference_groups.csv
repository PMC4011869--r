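level,name,mean,sd
group,AP,1.32,0.11
group,SI,1.37,0.07
group,AI,1.17,0.09
group,ML,0.62,0.16
subgroup,Mandible,1.22,0.03
subgroup,Anterior (Body),1.27,0.09
subgroup,Posterior (Ramus),1.45,0.01
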