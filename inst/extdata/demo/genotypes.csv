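individual_id,cohort,haplotype,L01,L02,L03,L04,L05
2010_001,2010,4,9/9,5/5,7/7,7/7,5/5
2010_002,2010,2,8/8,2/6,8/6,5/4,2/5
2010_003,2010,4,9/9,5/5,7/7,7/7,5/5
2010_004,2010,5,4/4,6/6,2/2,3/3,2/2
2010_005,2010,5,8/8,8/8,1/1,4/9,2/2
2010_006,2010,5,3/4,8/6,1/6,4/3,2/2
2010_008,2010,5,8/8,6/8,6/1,7/7,10/10
2010_010,2010,5,4/4,6/6,2/2,8/8,2/2
2010_011,2010,2,8/8,2/2,8/8,10/10,2/2
2010_012,2010,5,8/8,6/8,9/9,4/4,10/5
2010_013,2010,5,4/4,6/6,2/2,3/3,2/2
2010_015,2010,5,4/4,6/6,2/2,3/3,2/2
2010_016,2010,5,8/8,6/6,2/6,8/4,2/10
2010_017,2010,5,4/4,6/6,2/2,3/3,2/2
2010_018,2010,4,9/9,5/5,7/7,7/7,5/5
2011_001,2011,4,8/4,4/2,8/8,2/5,10/10
2011_002,2011,5,2/8,8/8,2/1,4/4,5/10
2011_003,2011,5,8/8,8/8,1/1,4/4,10/2
2011_004,2011,2,8/9,2/7,8/8,2/2,10/2
2011_005,2011,4,8/8,4/4,8/8,10/10,10/10
2011_006,2011,5,4/4,6/6,2/2,3/3,2/2
2011_007,2011,5,3/8,6/8,1/6,7/2,10/5
2011_010,2011,4,8/8,4/4,1/1,2/2,10/10
2011_011,2011,5,8/8,8/8,2/1,4/4,10/10
2011_012,2011,5,2/2,8/8,1/2,8/4,2/2
2011_013,2011,4,8/8,4/2,1/1,2/10,10/10
2011_014,2011,5,8/2,8/8,1/1,4/4,10/10
2011_015,2011,5,8/3,8/6,1/1,4/7,10/2
2011_016,2011,5,8/3,4/8,6/1,4/7,5/10
2011_018,2011,4,8/4,4/4,1/8,2/2,10/10
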