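subgroup	strain	closest_type	anib	ddh_below_70	reidentified
P. japonica	P. putida CSV86	P. japonica	86.94	FALSE	Pseudomonas sp. #1
P. reidholzensis	P. putida 02C-26	P. shirazensis	97.25	FALSE	P. shirazensis
P. guariconensis	P. putida IEC33019	P. guariconensis	91.47	FALSE	Pseudomonas sp. #2
P. guariconensis	P. putida WP4-W18-CRE-03	P. guariconensis	99.38	FALSE	P. guariconensis
P. guariconensis	P. putida WP8-W18-CRE-01		99.47	FALSE	
P. wayambapalatensis	P. putida NX-1	P. wayambapalatensis	94.69	FALSE	Pseudomonas sp. #3
P. wayambapalatensis	P. putida PC2		94.78	FALSE	
P. wayambapalatensis	Pseudomonas sp. RW3S2	P. wayambapalatensis	99.21	FALSE	P. wayambapalatensis
P. wayambapalatensis	Pseudomonas sp. RW10S2		99.26	FALSE	
P. farsensis	Pseudomonas sp. SWRI51	P. farsensis	98.65	FALSE	P. farsensis
P. mosselii	Pseudomonas sp. 250J	P. peradeniyensis	96.15	TRUE	Pseudomonas sp. #4
P. mosselii	Pseudomonas sp. BW16M2	P. peradeniyensis	96.59	FALSE	P. peradeniyensis
P. plecoglossicida	P. putida GM84	P. plecoglossicida	91.13	FALSE	Pseudomonas sp. #5
P. plecoglossicida	P. putida GIMC5401-PPKH-115	P. plecoglossicida	87.01	FALSE	Pseudomonas sp. #6
P. plecoglossicida	P. putida BR-PH17	P. plecoglossicida	86.75	FALSE	Pseudomonas sp. #7
P. plecoglossicida	P. putida W619		85.75	FALSE	
P. vlassakiae	P. putida AA7	P. vlassakiae	90.88	FALSE	Pseudomonas sp. #8
P. vlassakiae	P. putida W5	P. vlassakiae	91.64	FALSE	Pseudomonas sp. #9
P. capeferrum	Pseudomonas sp. SWRI68	P. capeferrum	98.66	FALSE	P. capeferrum
P. capeferrum	Pseudomonas sp. SWRI59		98.65	FALSE	
P. capeferrum	P. putida E41	P. kermanshahensis	97.48	FALSE	P. kermanshahensis
P. capeferrum	P. putida E46		97.55	FALSE	
P. capeferrum	Pseudomonas sp. SWRI50		99.39	FALSE	
P. capeferrum	Pseudomonas sp. SWRI67		99.99	FALSE	
P. putida	P. putida SY153	P. jutendi	98.15	FALSE	P. jutendi
P. putida	P. putida TIJ-51		97.77	FALSE	
P. putida	P. putida GB-1	P. alloputida	90.49	FALSE	Pseudomonas sp. #10
P. putida	P. putida PP112420		90.54	FALSE	
P. putida	P. putida S13-1-2	P. putida	94.55	FALSE	Pseudomonas sp. #11
P. putida	P. putida KF715	P. putida	93.73	FALSE	Pseudomonas sp. #12
P. putida	P. putida ZXPA-20		93.40	FALSE	
P. putida	P. putida H8234		93.33	FALSE	
P. putida	P. putida B1		93.40	FALSE	
P. putida	P. putida R51	P. alloputida	95.00	TRUE	Pseudomonas sp. #13
P. putida	P. putida BS3701	P. alloputida	96.67	FALSE	P. alloputida
P. putida	P. putida MX-2		96.49	FALSE	
P. putida	P. putida LS46		96.44	FALSE	
P. putida	P. putida 15420352		96.42	FALSE	
P. putida	P. putida YC-AE1		96.40	FALSE	
P. putida	P. putida T25-27		96.51	FALSE	
P. putida	P. monteilii 170620603RE	P. kurunegalensis	99.45	FALSE	P. kurunegalensis
P. putida	P. monteilii 170918607		99.44	FALSE	
P. putida	P. monteilii STW0522-72		99.64	FALSE	
P. putida	P. monteilii FDAARGOS171		99.77	FALSE	
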