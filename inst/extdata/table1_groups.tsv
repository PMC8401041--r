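section	group	subgroup	species	n_species	rpod_range	anib_range
existing	P. aeruginosa G		P. aeruginosa;P. citronellolis;P. delhiensis;P. humi;P. jinjuensis;P. knackmussii;P. nicosulfuronedens;P. nitritireducens;P. nitroreducens;P. panipatensis	10	77.85-95.98	80.57-94.48
existing	P. anguilliseptica G		P. anguilliseptica;P. benzenivorans;P. borbori;P. cuatrocienegasensis;P. guineae;P. leptonychotis;P. marincola;P. peli;P. segetis;P. taeanensis	10	72.33-91.58	76.68-89.45
existing	P. fluorescens G			134	-	-
existing	P. fluorescens G	P. asplenii SG	P. agarici;P. asplenii;P. batumici;P. fuscovaginae;*P. vanderleydeniana	5	84.41-89.66	84.10-88.35
existing	P. fluorescens G	P. chlororaphis SG	P. chlororaphis subsp. aurantiaca;P. chlororaphis subsp. aureofaciens;P. chlororaphis subsp. chlororaphis;P. chlororaphis subsp. piscium	4	97.83-98.45	94.73-96.95
existing	P. fluorescens G	P. corrugata SG	*P. alvandae;P. beijieensis;P. brassicacearum;P. corrugata;P. kilonensis;*P. marvdashtae;P. mediterranea;*P. tehranensis;P. thivervalensis;P. viciae;*P. zanjanensis;*P. zarinae	12	89.75-97.36	85.55-95.75
existing	P. fluorescens G	P. fluorescens SG	P. allii;P. antartica;*P. asgharzadehiana;P. aylmerense;*P. azadiae;P. azotoformans;P. canadensis;P. carnis;P. cedrina subsp. cedrina;P. cedrina subsp. fulgida;P. costantinii;P. cremoris;P. cyclaminis;P. edaphica;P. extremaustralis;P. extremorientalis;P. fildesensis;P. fluorescens;P. grimontii;P. haemolytica;P. kairouanesis;P. karstica;*P. khavaziana;P. kitaguniensis;P. lactis;P. libanensis;P. lurida;P. marginalis;P. nabeulensis;P. orientalis;P. palleroniana;P. panacis;P. paracarnis;P. paralactis;P. pisciculturae;P. poae;P. rhodesiae;*P. salmasensis;P. salomonii;P. simiae;P. sivasensis;P. spelaei;P. synxantha;P. tolaasii;*P. tritici;P. trivialis;P. veronii;P. yamanorum	48	85.16-98.91	83.52-95.68
existing	P. fluorescens G	P. fragi SG	P. bubulae;P. deceptionensis;P. endophytica;P. fragi;P. helleri;P. lundensis;P. psychrophila;P. saxonica;P. taetrolens;P. versuta;P. weihenstephanensis	11	83.00-97.67	80.50-90.49
existing	P. fluorescens G	P. gessardii SG	P. brennerii;P. gessardii;P. mucidolens;P. proteolytica;*P. shahriarae	5	90.57-97.53	85.57-92.54
existing	P. fluorescens G	P. jessenii SG	*P. asgharzadehiana;*P. azerbaijanoccidens;P. izuensis;P. jessenii;P. laurylsulfatiphila;P. laurylsulfatovorans;P. mohnii;P. moorei;P. reinekei;P. umsongensis;P. vancouverensis	11	90.37-100	84.91-95.51
existing	P. fluorescens G	P. koreensis SG	P. atacamensis;P. atagosis;P. baetica;*P. bananamidigenes;*P. botevensis;P. crudilactis;*P. ekonensis;P. glycinae;P. granadensis;*P. hamedanensis;P. helmanticensis;*P. iranensis;*P. khorasanensis;P. koreensis;P. kribbensis;*P. monsensis;P. moraviensis;P. neuropathica;*P. siliginis;*P. tensinigenes;*P. triticicola;*P. zeae	22	85.40-99.53	82.48-96.09
existing	P. fluorescens G	P. mandelii SG	P. arsenicoxydans;*P. farris;P. frederiksbergensis;P. gregormendelii;P. lini;P. mandelii;P. migulae;P. mucoides;P. piscium;P. prosekii;P. silesiensis	11	91.04-96.89	84.68-94.29
existing	P. fluorescens G	P. protegens SG	P. aestus;P. protegens;P. saponiphila;*P. sessilinigenes	4	89.52-95.57	86.41-91.86
existing	P. fluorescens G	P. kielensis SG	P. kielensis	1	-	-
existing	P. linyingensis G		P. guangdongensis;P. linyingensis;P. oryzae;P. sagittaria	4	79.94-93.85	85.19-92.01
existing	P. lutea G		P. abietaniphila;P. bohemica;P. graminis;P. lutea	4	83.31-88.30	81.89-85.81
existing	P. oleovorans G		P. alcaliphila;P. chaetoceroseae;P. chengduensis;P. composti;P. guguanensis;P. hydrolytica;P. indoloxydans;P. khazarica;P. mendocina;P. oleovorans;P. pseudoalcaligenes;P. sediminis;P. sihuisensis;P. toyotomiensis	14	88.51-98.76	86.06-95.79
existing	P. oryzihabitans G		P. asuensis;P. duriflava;P. luteola;P. oryzihabitans;P. psychrotolerans;P. rhizoryzae;P. zeshuii	7	66.46-94.18	73.64-88.62
existing	P. pertucinogena G		P. abyssi;P. aestusnigri;P. bauzanensis;P. formosensis;P. gallaeciencis;P. jilinensis;P. litoralis;P. oceani;P. pachastrellae;P. pelagia;P. pertucinogena;P. phragmitis;P. populi;P. profundi;P. sabulinigri;P. salegens;P. salina;P. saliphila;P. saudimassiliensis;P. xiamenensis;P. xinjiangensis;P. yangmingensis	22	64.53-92.98	74.65-89.65
existing	P. putida G			51	-	-
existing	P. putida G	P. akappagea SG	P. akappagea	1	-	-
existing	P. putida G	P. japonica SG	P. brassicae;P. defluvii;P. huaxiensis;P. japonica;P. laurentiana;P. qingdaonensis	6	82.69-95.05	80.96-91.58
existing	P. putida G	P. vranovensis SG	P. alkylphenolica;P. donghuensis;P. hutmensis;P. tructae;P. vranovensis;P. wadenswillerensis	6	84.23-94.10	84.52-93.03
existing	P. putida G	P. cremoricolorata SG	P. cremoricolorata	1	-	-
existing	P. putida G	P. reidholzensis SG	P. reidholzensis;*P. shirazensis;*P. urmiensis	3	85.78-92.89	84.27-86.77
existing	P. putida G	P. guariconensis SG	P. guariconensis	1	-	-
existing	P. putida G	P. wayambapalatensis SG	*P. wayambapalatensis	1	-	-
existing	P. putida G	P. farsensis SG	*P. farsensis	1	-	-
existing	P. putida G	P. xanthosomae SG	*P. fakonensis;*P. xanthosomae	2	97.84	95.06
existing	P. putida G	P. mosselii SG	P. entomophila;*P. maumuensis;P. mosselii;*P. muyukensis;*P. peradeniyensis;P. sichuanensis;P. soli;*P. xantholysinigenes	8	87.48-95.35	87.35-94.87
existing	P. putida G	P. taiwanensis SG	P. taiwanensis	1	-	-
existing	P. putida G	P. plecoglossicida SG	P. plecoglossicida	1	-	-
existing	P. putida G	P. vlassakiae SG	P. hunanensis;*P. promysalinigenes;*P. vlassakiae	3	89.34-93.04	86.58
existing	P. putida G	P. capeferrum SG	P. capeferrum;*P. kermanshahensis	2	93.01	90.26
existing	P. putida G	P. putida SG	P. alloputida;*P. anuradhapurensis;P. asiatica;P. fulva;P. inefficax;P. juntendi;*P. kurunegalensis;P. monteilii;*P. oryzicola;P. parafulva;P. putida;P. pyomelaminifaciens;P. persica;P. shirazica	14	85.32-97.99	82.66-95.79
existing	P. resinovorans G		P. furukawaii;P. lalkuanensis;P. mangiferae;P. otitidis;P. resinovorans	5	81.47-90.46	79.25-87.84
existing	P. straminea G		P. argentinensis;P. daroniae;P. dryadis;P. flavescens;P. punonensis;P. seleniipraecipitans;P. straminea	7	86.02-93.63	82.83-88.54
existing	P. stutzeri G		P. azotofigens;P. balearica;P. chloritidismutans;P. kirkiae;P. kunmingensis;P. nitritititolerans;P. nosocomialis;P. perfectomarina;P. saudiphocaensis;P. songnenensis;P. stutzeri;P. urumqiensis;P. xanthomarina;P. zhaodongensis	14	73.60-89.69	76.39-88.15
existing	P. syringae G		P. amygdali;P. asturieensis;P. avellanae;P. cannabina;P. caricapapayae;P. caspiana;P. cerasi;P. cichorii;P. congelans;P. coronafaciens;P. ficuserectae;P. floridensis;P. meliae;P. ovata;P. savastanoi;P. syringae;P. tremae;P. viridiflava	18	78.36-99.54	78.20-94.57
newly_described	P. pohangensis G		P. mangrovi;P. pohangensis	2	67.02	77.07
newly_described	P. massiliensis G		P. massiliensis;P. typographi	2	80.53	76.86
newly_described	P. rhizosphaerae G		P. baltica;P. coleopterorum;P. rhizosphaerae	3	91.89-94.70	88.28-90.55
orphan	P. indica G		P. indica	1	-	-
orphan	P. kuykendallii G		P. kuykendallii	1	-	-
orphan	P. thermotolerans G		P. thermotolerans	1	-	-
orphan	P. flexibilis G		P. flexibilis;P. tuomuerensis	2	-	-
orphan	P. fluvialis G		P. fluvialis;P. pharmacofabricae	2	-	-
orphan	P. alcaligenes G		P. alcaligenes	1	-	-
orphan	P. matsuisoli G		P. matsuisoli	1	-	-
orphan	P. turukhanskensis G		P. turukhanskensis	1	-	-
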