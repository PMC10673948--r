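sex,age_years,p5_kg,p50_kg,p95_kg
M,1,8.6,10.2,11.9
M,1.5,9.7,11.5,13.4
M,2,10.8,12.7,15.0
M,3,12.2,14.3,17.2
M,4,13.7,16.3,19.9
M,5,15.3,18.4,23.1
M,6,17.0,20.7,26.8
M,7,18.9,23.1,31.0
M,8,20.9,25.9,35.7
M,9,23.0,28.7,40.8
M,10,25.3,32.0,46.4
M,11,27.8,35.9,52.4
M,12,30.7,40.3,58.7
M,13,34.2,45.3,65.0
M,14,38.4,50.8,71.0
M,15,42.8,56.0,76.4
M,16,46.9,60.5,80.8
M,17,49.9,63.5,84.1
F,1,8.0,9.5,11.2
F,1.5,9.1,10.8,12.6
F,2,10.2,12.1,14.3
F,3,11.7,13.9,16.8
F,4,13.2,15.9,19.7
F,5,14.9,18.0,23.1
F,6,16.5,20.2,26.9
F,7,18.4,22.8,31.4
F,8,20.5,25.8,36.5
F,9,22.8,29.1,42.1
F,10,25.3,32.9,48.1
F,11,28.2,37.2,54.4
F,12,31.5,41.6,60.7
F,13,35.0,45.8,66.4
F,14,38.3,49.4,71.1
F,15,41.0,52.0,74.5
F,16,42.9,53.7,76.6
F,17,43.9,54.7,77.8
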