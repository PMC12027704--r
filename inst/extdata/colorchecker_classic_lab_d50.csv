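# ColorChecker 24-patch reference values, classic (pre-2015) chart vintage.
# CIELAB under illuminant D50, 2-degree observer; row-major chart order
# (row 1 starts at dark skin, row 4 is the neutral ramp).
index,name,L,a,b
1,dark skin,37.986,13.555,14.059
2,light skin,65.711,18.130,17.810
3,blue sky,49.927,-4.880,-21.925
4,foliage,43.139,-13.095,21.905
5,blue flower,55.112,8.844,-25.399
6,bluish green,70.719,-33.397,-0.199
7,orange,62.661,36.067,57.096
8,purplish blue,40.020,10.410,-45.964
9,moderate red,51.124,48.239,16.248
10,purple,30.325,22.976,-21.587
11,yellow green,72.532,-23.709,57.255
12,orange yellow,71.941,19.363,67.857
13,blue,28.778,14.179,-50.297
14,green,55.261,-38.342,31.370
15,red,42.101,53.378,28.190
16,yellow,81.733,4.039,79.819
17,magenta,51.935,49.986,-14.574
18,cyan,51.038,-28.631,-28.638
19,white 9.5,96.539,-0.425,1.186
20,neutral 8,81.257,-0.638,-0.335
21,neutral 6.5,66.766,-0.734,-0.504
22,neutral 5,50.867,-0.153,-0.270
23,neutral 3.5,35.656,-0.421,-1.231
24,black 2,20.461,-0.079,-0.973
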