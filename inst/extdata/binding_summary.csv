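ligand,docking_range,csp_range,hotspot,hotspot_sites,peak_csp_ppm,concentration
CMP,N247-Y255,N247-Y255,R252,4,0.087,1mM
LMWH,N247-Y255,N247-Y255,R252,6,0.087,80uM
LFcinB11,N247-Y255,N247-Y255,R252,7,0.151,60uM
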