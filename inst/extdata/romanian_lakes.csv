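lake_id,name,area_ha,county,origin,protected,morphologic_unit,W,R,A,a,S,T,I,C,slope,aspect,permeability,state
1,Voila,217,Brasov,Man made,yes,Fagaras Depression,0,5,3,2,1,1,0,2,1,5,3,semi_degraded
2,Snagov,422,Ilfov,Natural,yes,Snagov Plain,3,5,3,1,2,4,1,2,1,3,1,semi_degraded
3,Vacaresti,126,Dambovita,Man made,no,Targoviste Plain,3,5,5,2,1,3,3,4,1,3,1,degraded
4,Vidraru,803,Arges,Man made,yes,Lovistei Mountains,2,5,1,1,2,4,0,1,4,5,1,semi_degraded
5,Tau,78,Sibiu,Man made,yes,Cindrel Mountains,2,5,1,1,1,4,0,1,4,5,1,semi_degraded
6,Firiza,104,Maramures,Man made,no,Ignis Mountains,2,5,1,1,2,4,1,1,3,5,1,semi_degraded
7,Surduc,352,Timis,Man made,yes,Lugojului Hills,3,5,3,2,2,3,0,1,3,3,1,semi_degraded
8,Taut,176,Arad,Man made,yes,Tauti Depression,3,5,3,2,2,3,0,1,3,3,1,semi_degraded
9,Bezid,162,Mures,Man made,yes,Tarnavelor Sub-Carpathian Region,0,5,1,4,1,3,1,1,3,5,1,semi_degraded
10,Lugasu,325,Bihor,Man made,yes,Vad-Oradea Depression,3,5,3,2,1,5,0,4,1,5,1,semi_degraded
11,Stiucilor,31,Cluj,Natural,yes,Sicului Hills,2,5,5,3,1,4,0,3,3,3,1,semi_degraded
12,Varsolt,324,Salaj,Man made,no,Simleu Depression,3,5,5,1,1,4,1,2,1,5,1,semi_degraded
13,Zanoaga Mare,6,Hunedoara,Natural,yes,Retezat Mountains,0,2,1,1,1,1,0,2,3,3,1,natural
14,Oltina,1958,Constanta,Natural,yes,Oltina Plateau,3,5,5,1,2,3,1,4,3,5,1,semi_degraded
15,Siutghiol,1756,Constanta,Natural,yes,Istria Plateau,2,5,3,1,2,5,3,4,2,3,1,semi_degraded
16,Rosu,165,Harghita,Natural,yes,Hasmas Mountains,2,5,1,1,1,1,0,1,4,5,1,semi_degraded
17,Lala,44,Bistrita-Nasaud,Natural,yes,Rodna Mountains,3,2,1,1,1,1,0,1,4,3,1,natural
18,Bistret,409,Dolj,Natural,yes,Bistretului Alluvial Plain,3,2,1,1,1,4,1,5,1,3,5,semi_degraded
19,Potcoava,90,Tulcea,Natural,yes,Danube Delta,2,1,1,1,2,0,0,1,1,3,1,natural
20,Merhei,1385,Tulcea,Natural,yes,Danube Delta,0,1,1,1,2,0,0,1,1,3,1,natural
21,Calimanesti,801,Galati,Man made,yes,Siretului Plain,2,5,5,1,2,3,3,2,1,5,1,semi_degraded
22,Siriu,195,Buzau,Man made,yes,Podu Calului Mountains,0,5,1,1,1,4,3,1,4,5,1,semi_degraded
23,Brates,2199,Galati,Man made,yes,Brates Alluvial Plain,3,5,5,1,2,5,3,5,1,5,5,degraded
24,Poiana Uzului,265,Bacau,Man made,no,Slanicului Hills,2,5,1,1,2,3,1,1,3,5,5,semi_degraded
25,Amara,700,Braila,Natural,yes,Buzaului Alluvial Plain,3,5,5,1,2,4,0,4,1,5,1,semi_degraded
26,Razim,39569,Tulcea,Natural,yes,Danube Delta,0,5,1,1,4,4,0,4,1,3,1,semi_degraded
27,Solesti,374,Vaslui,Man made,no,Repedea-Zapodeni Plateau,3,5,5,2,1,4,0,3,3,5,1,semi_degraded
28,Bratul Dunarea Veche,186,Mehedinti,Natural,yes,Drobeta-Bala Corridor,1,1,1,2,1,4,5,1,1,5,1,semi_degraded
29,Izvorul Muntelui,2843,Neamt,Man made,yes,Ceahlau Mountains,2,5,1,1,2,4,0,1,3,3,1,semi_degraded
30,Stanca Costesti,4954,Botosani,Man made,yes,Prut Corridor,0,5,3,1,1,0,0,4,1,3,1,semi_degraded
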