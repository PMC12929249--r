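class,n,ltfu_count,high_vl_count
1,874,111,241
2,804,149,320
3,670,92,186
4,511,86,101
5,758,82,241
6,699,100,213
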