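region,marker,genotype,n,mean_pod,range_low,range_high
YHRVWWR,POD-7D1,TaPod-D1b,83,689.3,431.3,954.8
YHRVWWR,POD-7D6,TaPod-D1a,64,654.6,461.4,874.2
NWWR,POD-7D1,TaPod-D1b,32,757.8,526.4,1111.8
NWWR,POD-7D6,TaPod-D1a,45,706.7,516.6,850.3
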