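# Macromolecule / lipid components modeled as single broad Gaussian lines.
# Centers follow the LCModel naming convention (name encodes ppm). version: 1
name,center_ppm,fwhm_ppm
MM09,0.91,0.14
Lip09,0.89,0.15
MM12,1.21,0.15
Lip13a,1.30,0.09
Lip13b,1.28,0.19
MM14,1.43,0.17
MM17,1.67,0.15
MM20,2.08,0.15
Lip20,2.04,0.15
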