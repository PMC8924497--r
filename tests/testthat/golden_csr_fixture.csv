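la,ldmc,sla,c_pct,s_pct,r_pct
2025,25,20,36.399559843579794,34.687394647678744,28.913045508741455
60,15,45,3.964122256355092,0.0,96.0358777436449
200000,25,15,85.1962281243807,9.858606531763787,4.945165343855518
500,55,5,13.037202035998689,86.96279796400131,0.0
4000,30,16,43.05944225464601,40.698083893710695,16.24247385164329
894205,40,10,79.75599568926033,19.97547621889772,0.26852809184194554
1,50,8,0.0,100.0,0.0
12000,35,12,57.00954330610769,37.95371896733897,5.036737726553351
350,18,38,16.927546373612287,9.49807421049067,73.57437941589706
75000,22,18,83.40993177857597,8.163987140008464,8.42608108141557
900,60,4,16.547605757212526,83.45239424278746,0.0
150,12,55,8.779020044473617,0.0,91.22097995552637
30000,45,9,64.06887147816275,35.93112852183726,0.0
5500,28,22,44.98766972260015,31.629537513085996,23.382792764313848
2500,33,14,35.979593913990996,51.17064156010462,12.849764525904387
250000,30,11,84.50397340587713,14.120551551380576,1.3754750427422913
40,65,6,0.9734542062242685,99.02654579377574,0.0
8000,20,30,55.784718018736484,11.555009899135728,32.66027208212779
1200,48,7,22.69188629365795,77.30811370634206,0.0
600,38,25,14.080392929788832,55.94735879481012,29.972248275401043
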