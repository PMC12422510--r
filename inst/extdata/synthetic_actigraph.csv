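--------- Data File Created By ActiGraph ---------
Serial Number: SYN0001
Start Time 09:00:00
Start Date 03/05/2012
Epoch Period (hh:mm:ss) 00:01:00
---------------------------------------------------
0
32
110
950
2500
3100
80
0
0
45
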