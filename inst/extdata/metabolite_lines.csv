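# Simplified first-order multiplet table for the 3 T brain metabolite basis.
# Chemical shifts are standard literature values; each multiplet is collapsed
# to a single line at its center with relative amplitude equal to the number
# of contributing protons. version: 1
metabolite,center_ppm,relative_amplitude
Ala,1.470,3
Ala,3.780,1
Asp,2.660,1
Asp,2.800,1
Asp,3.890,1
Cr,3.027,3
Cr,3.913,2
PCr,3.029,3
PCr,3.930,2
GABA,1.890,2
GABA,2.280,2
GABA,3.010,2
Glc,3.230,1
Glc,3.400,1
Glc,3.460,1
Glc,3.530,1
Glc,3.700,1
Glc,3.880,1
Glc,5.220,1
Gln,2.130,2
Gln,2.450,2
Gln,3.750,1
Glu,2.040,2
Glu,2.340,2
Glu,3.740,1
GSH,2.150,2
GSH,2.550,2
GSH,2.930,2
GSH,3.770,2
GSH,4.560,1
GPC,3.212,9
GPC,3.660,2
GPC,3.900,1
GPC,4.310,2
PCh,3.208,9
PCh,3.580,2
PCh,4.160,2
Ins,3.270,1
Ins,3.520,2
Ins,3.610,2
Ins,4.050,1
Lac,1.310,3
Lac,4.100,1
NAA,2.008,3
NAA,2.490,1
NAA,2.670,1
NAA,4.380,1
NAAG,2.040,3
NAAG,2.190,2
NAAG,2.720,1
NAAG,4.130,1
NAAG,4.610,1
Tau,3.250,2
Tau,3.420,2
Cho,3.190,9
Cho,3.540,2
Cho,4.070,2
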