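amplicon,gene,start,end,declared_size
P1,TaPod-D1,-20,468,488
P2,TaPod-D1,450,1104,655
P3,TaPod-A2,-92,660,752
P4,TaPod-A2,462,1090,629
P5,TaPod-A3,,,574
P6,TaPod-B1,,,580
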