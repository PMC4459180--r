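station_id,date,lat,lon,f_poc,f_pic,f_bsi,f_lith,pal,f_th,region
S001,2013-06-16,70.2428722219774,-24.9689012253657,151.137363950993,10.0183197976983,26.8978513286622,2.39971276824756,,,
S002,2013-06-17,55.9780800190056,-41.1516244045924,142.501026075428,31.7810669388315,25.1796121461971,19.168684443142,,,
S003,2013-06-18,45.3020300298231,-2.75455376482569,156.111260938155,14.2097581843507,20.7236531932569,1.44045092151999,,,
S004,2013-06-19,46.390830197488,-51.9909469143022,116.216472731037,40.4462416221368,11.6252002757068,1.97645434359453,,,
S005,2013-06-20,65.5292583475821,-48.617660026066,77.7322084099579,32.7272108331626,20.041778186134,0.420964286956794,,,
S006,2013-06-21,46.8596616610885,-31.3512323342729,204.006901784066,88.9321693690997,9.34916689692853,3.07427781507208,,,
S007,2013-06-22,36.7514040751848,-23.3006253628992,122.575350531939,23.4750863207981,8.28620250454242,8.74693632584872,,,
S008,2013-06-23,34.7864653426223,-31.3157139252871,143.748492880214,22.169847554348,9.78377704773207,1.05265197322689,,,
S009,2013-06-24,-20.7293785642833,-23.4694502758794,85.9354818137952,21.6415178859076,49.2791006396079,8.7291961316801,,,
S010,2013-06-25,-61.8467950215563,24.8404126358218,106.729632714288,39.4331597616784,5.16227802391251,1.98568327353055,,,
S011,2013-06-26,-55.3973189322278,-9.98331691836938,173.06906034385,26.8572323861085,10.4744333265683,0.217506758945336,,,
S012,2013-06-27,-60.9257481060922,-11.4616778236814,83.3361607081658,54.9366774913826,40.5912639668902,8.62514786430977,,,
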