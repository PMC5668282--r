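month,month_name,raw_count
1,January,3698
2,February,3454
3,March,3846
4,April,3701
5,May,3412
6,June,3466
7,July,3283
8,August,3318
9,September,3154
10,October,3355
11,November,3298
12,December,3420
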