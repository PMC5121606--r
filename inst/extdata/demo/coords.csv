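"individual_id","x","y"
"2010_001",19.278610953842,8.15931470559801
"2010_002",11.9727411835548,14.3150952095707
"2010_003",18.7504065067865,8.30159894067479
"2010_004",9.91794477521578,2.87230937010776
"2010_005",10.6753195047592,0.542823242290534
"2010_006",10.8162300174263,0.887241864966627
"2010_008",11.1219906323567,4.98487917007012
"2010_010",10.5359065723173,2.25591566628994
"2010_011",11.3390219550537,14.8896651025517
"2010_012",11.2685530534307,5.22365100652309
"2010_013",9.91794477521578,2.87230937010776
"2010_015",9.91794477521578,2.87230937010776
"2010_016",10.4534834105505,2.21482265645398
"2010_017",9.91794477521578,2.87230937010776
"2010_018",18.7504065067865,8.30159894067479
"2011_001",10.5481870804807,15.5728403034454
"2011_002",10.7185975214793,1.10278793417581
"2011_003",11.1465713674131,5.28410370956088
"2011_004",10.9726681394695,13.6694083840428
"2011_005",10.9378228713147,15.5900639953615
"2011_006",11.4991896284952,5.83762447958502
"2011_007",9.75172104010846,4.65154693688303
"2011_010",10.981653733905,15.4745436496355
"2011_011",10.1265825995465,1.41221002967408
"2011_012",10.7031559953274,0.517282538869663
"2011_013",11.2893349504804,15.6171620484884
"2011_014",11.8551935325768,1.03376317746137
"2011_015",10.9508245255966,5.70852083966428
"2011_016",11.907401917147,4.77117498142833
"2011_018",10.5468060843082,15.7478271324539
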