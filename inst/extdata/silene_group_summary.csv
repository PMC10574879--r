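group,grouping,n_tubercles,W_mean,W_cv,W_min,W_max,H_mean,H_cv,H_min,H_max,S_mean,S_cv,S_min,S_max,kmax_mean,kmax_cv,kmax_min,kmax_max,kmean_mean,kmean_cv,kmean_min,kmean_max,ratio_mean,ratio_cv,ratio_min,ratio_max
rugose,type,268,83.3,24.8,31.1,174.0,20.7,35.5,6.8,42.0,49.8,25.8,22.5,89.7,41.4,47.1,14.5,150.4,26.9,41.3,9.4,69.0,1.6,30.8,1.0,3.9
echinate,type,128,72.0,23.1,31.0,127.0,43.6,49.7,13.0,100.0,124.3,52.2,40.0,394.3,118.7,63.8,17.3,477.0,44.2,48.3,6.7,126.7,3.1,77.0,0.27,18.4
Behenantha,subgenus,130,82.2,27.4,31.0,174.0,41.9,53.4,12.0,100.0,112.4,64.2,24.2,394.3,103.8,79.4,14.5,447.0,39.7,57.6,6.7,126.7,2.9,84.2,1.1,18.4
Silene,subgenus,263,78.4,23.9,31.1,129.0,21.4,37.9,6.8,45.6,55.1,35.4,22.4,128.1,48.2,57.1,17.0,167.0,29.0,42.0,9.4,69.0,1.7,33.3,0.3,3.9
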