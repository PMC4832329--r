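reaction	substrates	products	carbon_map	co2_losses	symmetric_products
glycolysis_cleavage	hexose	triose,triose	1:1<-1:3;1:2<-1:2;1:3<-1:1;2:1<-1:4;2:2<-1:5;2:3<-1:6		
ppp_oxidative	hexose	pentose	1:1<-1:2;1:2<-1:3;1:3<-1:4;1:4<-1:5;1:5<-1:6	1:1	
ppp_tk1	pentose,pentose	s7p,triose	1:1<-1:1;1:2<-1:2;1:3<-2:1;1:4<-2:2;1:5<-2:3;1:6<-2:4;1:7<-2:5;2:1<-1:3;2:2<-1:4;2:3<-1:5		
ppp_ta	s7p,triose	hexose,e4p	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-2:1;1:5<-2:2;1:6<-2:3;2:1<-1:4;2:2<-1:5;2:3<-1:6;2:4<-1:7		
ppp_tk2	pentose,e4p	hexose,triose	1:1<-1:1;1:2<-1:2;1:3<-2:1;1:4<-2:2;1:5<-2:3;1:6<-2:4;2:1<-1:3;2:2<-1:4;2:3<-1:5		
glycolysis_lower	triose	pyruvate	1:1<-1:1;1:2<-1:2;1:3<-1:3		
pdh	pyruvate	acetyl_coa	1:1<-1:2;1:2<-1:3	1:1	
pc	pyruvate	oaa	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-CO2_FIXED		
citrate_synthase	acetyl_coa,oaa	citrate	1:1<-1:1;1:2<-1:2;1:3<-2:2;1:4<-2:3;1:5<-2:4;1:6<-2:1		
citrate_to_akg	citrate	akg	1:1<-1:5;1:2<-1:4;1:3<-1:3;1:4<-1:2;1:5<-1:1	1:6	
akg_to_glutamate	akg	glutamate	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-1:4;1:5<-1:5		
glutamate_to_glutamine	glutamate	glutamine	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-1:4;1:5<-1:5		
akg_to_succinate	akg	succinate	1:1<-1:2;1:2<-1:3;1:3<-1:4;1:4<-1:5	1:1	1
succinate_to_malate	succinate	malate	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-1:4		
malate_to_oaa	malate	oaa	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-1:4		
malic_enzyme	malate	pyruvate	1:1<-1:1;1:2<-1:2;1:3<-1:3	1:4	
oaa_to_aspartate	oaa	aspartate	1:1<-1:1;1:2<-1:2;1:3<-1:3;1:4<-1:4		
pyruvate_to_lactate	pyruvate	lactate	1:1<-1:1;1:2<-1:2;1:3<-1:3		
pyruvate_to_alanine	pyruvate	alanine	1:1<-1:1;1:2<-1:2;1:3<-1:3		
acetate_to_acetyl	acetate	acetyl_coa	1:1<-1:1;1:2<-1:2		
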