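finesgs genotypes
L01
L02
L03
L04
L05
pop
2010_001 ,  009009 005005 007007 007007 005005
2010_002 ,  008008 002006 008006 005004 002005
2010_003 ,  009009 005005 007007 007007 005005
2010_004 ,  004004 006006 002002 003003 002002
2010_005 ,  008008 008008 001001 004009 002002
2010_006 ,  003004 008006 001006 004003 002002
2010_008 ,  008008 006008 006001 007007 010010
2010_010 ,  004004 006006 002002 008008 002002
2010_011 ,  008008 002002 008008 010010 002002
2010_012 ,  008008 006008 009009 004004 010005
2010_013 ,  004004 006006 002002 003003 002002
2010_015 ,  004004 006006 002002 003003 002002
2010_016 ,  008008 006006 002006 008004 002010
2010_017 ,  004004 006006 002002 003003 002002
2010_018 ,  009009 005005 007007 007007 005005
pop
2011_001 ,  008004 004002 008008 002005 010010
2011_002 ,  002008 008008 002001 004004 005010
2011_003 ,  008008 008008 001001 004004 010002
2011_004 ,  008009 002007 008008 002002 010002
2011_005 ,  008008 004004 008008 010010 010010
2011_006 ,  004004 006006 002002 003003 002002
2011_007 ,  003008 006008 001006 007002 010005
2011_010 ,  008008 004004 001001 002002 010010
2011_011 ,  008008 008008 002001 004004 010010
2011_012 ,  002002 008008 001002 008004 002002
2011_013 ,  008008 004002 001001 002010 010010
2011_014 ,  008002 008008 001001 004004 010010
2011_015 ,  008003 008006 001001 004007 010002
2011_016 ,  008003 004008 006001 004007 005010
2011_018 ,  008004 004004 001008 002002 010010
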