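# SYNTHETIC stand-ins for the 14 CIE 13.3 test-color samples.
# These are NOT the official tabulated reflectances: each entry is a CIELAB
# anchor (D65, 2-degree observer) chosen to span the hue circle at moderate
# chroma (samples 1-8), plus four saturated samples (9-12), a skin tone (13)
# and a leaf green (14), mirroring the character of the official set. The
# package reconstructs a maximally smooth reflectance curve matching each
# anchor at load time; see the methods vignette.
index,name,L,a,b
1,light greyish red,61,22.7,8.3
2,dark greyish yellow,61,12.5,21.7
3,strong yellow green,61,-8.7,23.4
4,moderate yellowish green,61,-23.5,8.6
5,light bluish green,61,-22.6,-10.7
6,light blue,61,-10.6,-22.6
7,light violet,61,8.7,-23.4
8,light reddish purple,61,23.5,-8.6
9,strong red,45,65.8,38.0
10,strong yellow,80,-6.9,79.7
11,strong green,52,-46.0,38.6
12,strong blue,35,7.8,-44.3
13,light skin,65,16.7,17.3
14,moderate olive green,40,-19.3,23.0
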