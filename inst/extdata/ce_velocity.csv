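velocity_mm_per_s,mean_ce_percent,sd_ce_percent,n,source
4,85.0,3.6,3,"in vitro flow capture assay, velocity sweep"
20,68.7,4.7,3,"in vitro flow capture assay, velocity sweep"
100,11.3,4.5,3,"in vitro flow capture assay, velocity sweep"
500,1.6,0.75,3,"in vitro flow capture assay, velocity sweep"
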