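patch_id,country,n_respondents,area_2000_ha,area_2022_vs2000_ha,area_2010_ha,area_2022_ha,pct_decreased_5y,pct_increased_5y,pct_decreased_10y,pct_increased_10y
Agou,Togo,351,NA,NA,2346.0,2280.9,95,NA,93,NA
Elavagnon-Todji,Togo,306,NA,NA,680.8,648.4,94,NA,95,NA
Koui,Togo,150,NA,NA,130.9,125.6,28,55,30,54
Ewe-Adakplame,Benin,307,619,505,586.9,505.4,92,NA,93,NA
Hlanzoun,Benin,312,547,549,568.4,548.6,33,45,35,46
Iko,Nigeria,344,NA,NA,3554.2,3423.5,82,NA,77,NA
Ikot,Nigeria,377,NA,NA,1270.7,1253.0,65,NA,65,NA
Mbangassina,Cameroon,302,NA,NA,1007.0,991.2,97,NA,94,NA
Ngam-Kondomeyos,Cameroon,172,NA,NA,1285.0,1283.9,97,NA,95,NA
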