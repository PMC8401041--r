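species	year
P. citronellolis	1969
P. humi	2019
P. nitroreducens	1973
P. nitritireducens	2019
P. oleovorans	1940
P. pseudoalcaligenes	1966
P. chengduensis	2014
P. sihuiensis	2014
P. oryzihabitans	1985
P. psychrotolerans	2004
P. luteola	1990
P. zeshuii	2013
P. phragmitis	2019
P. jilinensis	2021
P. gallaeciensis	2017
P. abyssi	2018
P. asiatica	2019
P. pyomelaninifaciens	2020
P. shirazica	2020
P. chloritidismutans	2002
P. kunmingensis	2014
P. tremae	1997
P. coronafaciens	2017
P. amygdali	1969
P. ficuserectae	1983
P. meliae	1984
P. savastanoi	1982
P. asplenii	1966
P. fuscovaginae	1983
P. veronii	1996
P. panacis	2005
P. flexibilis	1977
P. tuomuerensis	2007
P. fluvialis	2018
P. pharmacofabricae	2019
P. mosselii	2002
P. entomophila	2006
P. soli	2013
P. sichuanensis	2019
P. peradeniyensis	2021
P. maumuensis	2022
P. muyukensis	2022
P. xantholysinigenes	2021
P. putida	1889
P. fulva	1963
P. monteilii	1997
P. parafulva	2003
P. alloputida	2021
P. juntendi	2019
P. capeferrum	2014
P. kermanshahensis	2021
P. japonica	2008
P. vranovensis	2006
P. reidholzensis	2018
P. plecoglossicida	2000
P. taiwanensis	2010
P. guariconensis	2013
P. wayambapalatensis	2021
P. farsensis	2021
P. cremoricolorata	2001
P. akappagea	2018
P. vlassakiae	2021
P. hunanensis	2022
P. promysalinigenes	2021
P. xanthosomae	2021
P. fakonensis	2021
P. shirazensis	2021
P. urmiensis	2021
P. kurunegalensis	2021
P. anuradhapurensis	2021
P. oryzicola	2021
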