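category,core,n_total,n_healthy,n_dementia,centroid_healthy_mean,centroid_healthy_sem,centroid_dementia_mean,centroid_dementia_sem,p_value
Sleeping,TRUE,512,234,278,55.28,3.9,90.33,11.5,0.009
Grooming,TRUE,395,211,184,49.33,3.3,84.52,14.6,0.028
Toileting,TRUE,614,276,338,59.10,6.0,100.03,10.4,0.002
GettingReadyForBed,TRUE,387,208,179,55.27,3.2,104.94,13.3,0.001
Cooking,TRUE,408,221,187,54.35,4.4,106.6,9.5,0.001
Eating,TRUE,548,231,317,54.73,3.8,103.6,16.7,0.028
WatchingTV,TRUE,644,317,327,47.03,2.3,77.92,7.3,0.003
SeatedActivity,TRUE,342,162,180,58.75,4.5,105.84,8.1,0.001
Visitors,FALSE,416,85,331,NA,NA,NA,NA,NA
OutOfHome,FALSE,296,152,144,NA,NA,NA,NA,NA
Total,NA,4562,2097,2465,NA,NA,NA,NA,NA
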