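Locus,Chromosome,Map_cM
D3S1358,3,67.1789
vWA,12,15.63031
D16S539,16,
CSF1PO,5,154.43395
TPOX,2,1.6661
D8S1179,8,136.44313
D21S11,21,14.64555
D18S51,18,88.9205
D2S441,2,90.47903
D19S433,19,51.72618
TH01,11,4.48933
FGA,4,156.81293
D22S1045,22,46.21362
D5S818,5,126.67284
D13S317,13,79.83074
D7S820,7,100.2012
SE33,6,95.4492
D10S1248,10,
D1S1656,1,
D12S391,12,27.57129
D2S1338,2,223.4832
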