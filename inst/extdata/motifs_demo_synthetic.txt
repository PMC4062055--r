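// synthetic demonstration motif count matrices (TRANSFAC-like)
// NOT derived from any licensed motif database
ID CTCF_like_01
PO A C G T
01 1 17 1 1
02 1 17 1 2
03 2 1 17 1
04 1 17 1 1
05 2 1 17 1
06 5 5 5 5
07 1 1 17 2
08 1 1 17 1
09 5 5 5 5
10 1 1 17 1
11 2 1 17 1
12 1 17 1 1
13 17 1 1 2
14 1 1 17 1
//
ID CTCF_like_02
PO A C G T
01 1 17 1 2
02 1 17 1 1
03 17 1 1 2
04 1 2 17 1
05 1 17 1 1
06 17 2 1 1
07 1 1 17 1
08 1 1 17 1
09 1 2 17 1
10 1 2 17 1
11 1 1 17 1
12 1 17 2 1
13 1 2 17 1
14 1 17 1 1
15 1 1 1 17
//
ID SP1_like_01
PO A C G T
01 2 1 17 1
02 1 1 17 2
03 1 1 17 1
04 2 1 17 1
05 1 17 1 1
06 1 2 17 1
07 1 1 17 2
08 2 1 17 1
09 1 1 17 1
//
ID SP1_like_02
PO A C G T
01 1 1 17 1
02 1 1 17 1
03 1 1 17 1
04 1 1 17 1
05 1 1 17 2
06 2 17 1 1
07 2 1 17 1
08 1 1 17 1
09 1 1 17 1
10 2 1 17 1
11 2 1 1 17
//
ID RFX_like_01
PO A C G T
01 2 1 17 1
02 1 1 1 17
03 1 1 1 17
04 2 1 17 1
05 1 17 1 1
06 1 17 1 1
07 17 1 1 1
08 1 1 1 17
09 1 1 17 1
10 1 1 17 1
11 1 17 1 1
12 17 1 2 1
13 17 1 1 2
14 1 17 1 1
//
ID RFX_like_02
PO A C G T
01 1 1 17 2
02 1 1 1 17
03 1 1 1 17
04 1 1 17 2
05 1 17 1 1
06 1 17 1 2
07 5 5 5 5
08 1 1 1 17
09 1 1 17 1
10 1 1 17 2
11 5 5 5 5
12 17 1 1 1
13 17 1 1 1
14 2 17 1 1
//
ID MECP2_like_01
PO A C G T
01 1 17 1 1
02 1 17 1 1
03 17 2 1 1
04 1 17 1 1
05 1 17 2 1
06 17 1 1 1
07 1 17 1 2
08 1 1 17 1
//
ID EBOX_like_01
PO A C G T
01 1 17 1 2
02 17 1 1 1
03 1 17 1 1
04 1 1 17 1
05 1 1 1 17
06 2 1 17 1
//
ID GATA_like_01
PO A C G T
01 17 1 1 1
02 1 1 17 1
03 17 1 2 1
04 1 1 1 17
05 17 1 2 1
06 17 1 1 1
07 1 2 17 1
08 17 2 1 1
//
ID NFKB_like_01
PO A C G T
01 1 1 17 1
02 1 1 17 1
03 1 1 17 1
04 17 1 2 1
05 1 17 1 1
06 1 2 1 17
07 1 1 1 17
08 1 1 1 17
09 1 17 1 1
10 1 17 2 1
//
ID CREB_like_01
PO A C G T
01 1 1 1 17
02 1 1 17 1
03 17 1 1 1
04 2 17 1 1
05 2 1 17 1
06 1 2 1 17
07 1 17 1 1
08 17 1 1 2
//
ID AP1_like_01
PO A C G T
01 1 1 1 17
02 1 1 17 1
03 17 1 1 2
04 2 17 1 1
05 1 2 1 17
06 1 17 1 1
07 17 1 2 1
//
ID ETS_like_01
PO A C G T
01 17 1 1 1
02 1 17 1 1
03 2 17 1 1
04 1 1 17 1
05 1 1 17 1
06 17 1 1 1
07 17 1 1 1
08 1 1 17 1
09 1 1 1 17
//
ID RUNX_like_01
PO A C G T
01 1 1 1 17
02 1 1 17 1
03 1 1 1 17
04 1 1 17 1
05 1 1 17 2
06 1 1 1 17
07 2 1 1 17
08 1 1 1 17
//
ID YY1_like_01
PO A C G T
01 1 17 1 1
02 17 1 1 1
03 17 1 1 1
04 1 1 17 2
05 17 1 1 1
06 1 1 1 17
07 1 1 17 1
08 1 2 17 1
09 1 17 1 2
10 1 1 17 1
11 1 1 17 1
12 1 17 1 1
//
ID NRF1_like_01
PO A C G T
01 1 1 17 1
02 1 17 1 1
03 1 1 17 1
04 1 17 2 1
05 17 1 1 1
06 1 2 1 17
07 1 1 17 1
08 2 17 1 1
09 2 1 17 1
10 1 17 2 1
//
ID IRF_like_01
PO A C G T
01 17 1 1 2
02 17 1 1 2
03 5 5 5 5
04 2 1 1 17
05 1 1 17 1
06 17 1 2 1
07 17 1 1 1
08 17 1 1 1
//
ID STAT_like_01
PO A C G T
01 1 1 1 17
02 1 2 1 17
03 1 17 2 1
04 1 17 1 1
05 1 17 1 1
06 1 1 17 1
07 1 1 17 1
08 17 1 1 1
09 17 1 2 1
//
ID SOX_like_01
PO A C G T
01 17 1 1 1
02 17 1 1 1
03 1 17 1 2
04 17 1 1 1
05 17 1 1 1
06 1 1 1 17
07 1 1 17 1
//
ID HOX_like_01
PO A C G T
01 1 2 1 17
02 17 1 2 1
03 17 1 1 1
04 1 1 1 17
05 1 1 1 17
06 17 1 1 1
//
ID KLF_like_01
PO A C G T
01 17 2 1 1
02 1 1 17 1
03 2 1 17 1
04 1 1 17 2
05 1 1 17 1
06 1 17 1 1
07 1 1 17 1
08 1 1 17 1
09 1 1 17 1
10 1 2 17 1
11 1 17 1 1
//
ID POU_like_01
PO A C G T
01 17 1 1 1
02 1 2 1 17
03 1 1 17 1
04 2 17 1 1
05 17 1 1 2
06 17 1 2 1
07 17 1 1 2
08 1 1 1 17
//
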