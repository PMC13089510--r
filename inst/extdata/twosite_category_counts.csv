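category_id,ce_matched,pprl_level,count
1,no,none,599471
2,no,permissive_only,9602
3,no,permissive_balanced,50916
4,no,all_three,34892
5,yes,none,4834
6,yes,permissive_only,3778
7,yes,permissive_balanced,104138
8,yes,all_three,41526
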