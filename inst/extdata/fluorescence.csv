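group,mean_photon_per_s,sd_photon_per_s,n,source
Mag,26222,5102,6,"ex vivo DiR fluorescence imaging, 24 h after infusion"
NonMag,9620,1930,6,"ex vivo DiR fluorescence imaging, 24 h after infusion"
PBS,6155,953,6,"ex vivo DiR fluorescence imaging, 24 h after infusion"
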