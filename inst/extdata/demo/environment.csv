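"individual_id","dsf","na","k","mg","n_total","p_total","field_capacity"
"2010_001",0.71819920042147,6.05308823976771,1.90917587963772,1.3839263256386,0.360469413291176,0.0446883745204592,0.236941882699846
"2010_002",0.390545214527329,5.11414110495709,1.98367741340676,0.803109871575667,0.305051349391573,0.0657898259455612,0.205756919364728
"2010_003",0.710896565877079,6.05406675741236,1.96941232519842,1.40148274365722,0.356998072864425,0.0479663294550489,0.236649184710054
"2010_004",0.501343463071737,5.40058108480151,1.19104814688059,0.649171707561059,0.37124153272797,0.0448475788969071,0.335600015289138
"2010_005",0.631422692004115,5.99645596806438,1.53241823566605,0.892108971902544,0.346900969364788,0.0340350213841252,0.274666228671578
"2010_006",0.606938971911317,5.93903857676434,1.46235696544297,0.802733245660455,0.344773755352723,0.0372772066006633,0.282392972989261
"2010_008",0.360483988395207,4.07738393541391,1.26581957733054,0.964983858095959,0.398866444991822,0.0609289373258434,0.328950790792966
"2010_010",0.532662502809598,5.58155332845697,1.22468463531406,0.618394906227051,0.361318126900323,0.0456867437201677,0.325322063563699
"2010_011",0.440043746229726,4.47475777054728,2.15363001092331,0.820744940486646,0.301299470145187,0.0693712686779119,0.207097665138602
"2010_012",0.348289123297097,4.01727010589486,1.30543305848932,1.02984760113881,0.399975862384629,0.0625750447372477,0.327965142910946
"2010_013",0.501343463071737,5.40058108480151,1.19104814688059,0.649171707561059,0.37124153272797,0.0448475788969071,0.335600015289138
"2010_015",0.501343463071737,5.40058108480151,1.19104814688059,0.649171707561059,0.37124153272797,0.0448475788969071,0.335600015289138
"2010_016",0.537905918332239,5.62445919941588,1.23016248436318,0.624479347014019,0.362765887971759,0.0448166110993839,0.325750907627653
"2010_017",0.501343463071737,5.40058108480151,1.19104814688059,0.649171707561059,0.37124153272797,0.0448475788969071,0.335600015289138
"2010_018",0.710896565877079,6.05406675741236,1.96941232519842,1.40148274365722,0.356998072864425,0.0479663294550489,0.236649184710054
"2011_001",0.487500173526309,3.71386215791762,2.44962142586826,0.704880963586634,0.296427698643499,0.0640817041096743,0.226830250798894
"2011_002",0.599140642565376,5.93499310126093,1.41364596528214,0.757980005925088,0.349968920053779,0.0383834263766878,0.292012403960539
"2011_003",0.351891498678721,3.97259435450972,1.31258473799827,1.03223956614179,0.40213129350553,0.0606495084476698,0.326582127513755
"2011_004",0.479057206932576,4.54212003794071,1.99319655186322,0.82831392575637,0.346206732589839,0.069321197976137,0.17406517555234
"2011_005",0.465901840334094,3.93363988584877,2.38418325246593,0.763356594433265,0.293615226294225,0.066076223990873,0.221177859604219
"2011_006",0.332414235438447,3.91494943851915,1.42969938255299,1.17994489846263,0.399467014344872,0.0639855423602169,0.324012572639098
"2011_007",0.399884420623832,4.27821235143168,1.21928434360563,0.802424319966312,0.386569541375065,0.0445080694593737,0.317945930417565
"2011_010",0.463452354109627,4.0087353785551,2.347436217045,0.775292742606583,0.294943619330642,0.0669001813882674,0.218790596647842
"2011_011",0.598516146982244,6.04844967084286,1.3499564190285,0.737567383155715,0.369741026821435,0.0373344267190925,0.313040369462076
"2011_012",0.631477196064104,5.98842532392435,1.53931705324486,0.898098262391162,0.345556059293377,0.0339854684387073,0.273060371406148
"2011_013",0.444384007628682,4.14276943125403,2.32410635659226,0.812906254733558,0.292140092715277,0.0669868736497104,0.217997901662649
"2011_014",0.534411511800542,5.73224248298218,1.49232529821939,0.798700358334558,0.305557479104116,0.0434676970144292,0.256548489271114
"2011_015",0.35151570508619,3.80257401251883,1.37648577027528,1.09795792658427,0.407964160700401,0.0561019688184218,0.319956840169671
"2011_016",0.330051645370602,4.33265826073355,1.23428957653864,0.970154287465928,0.383433707744743,0.071381931751778,0.330416016238238
"2011_018",0.486268873174215,3.64237340656301,2.49491612177037,0.688131696051861,0.293387181545553,0.0627897339530747,0.230363552560846
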