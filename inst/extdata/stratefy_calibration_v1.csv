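version,axis,source_trait,transform,transform_constant,curve,c0,c1,c2,c3,c4,output_min,output_range,invert
stratefy-global-v1,C,LA,sqrt_global_prop,894205,linear,-0.8678,1.6464,NA,NA,NA,0,57.3756711966087,FALSE
stratefy-global-v1,S,LDMC,logit_fraction,NA,double_exponential,1.3369,0.000010019,-0.0000000000022303,4.5835,-0.2328,-0.756451214853076,6.546531557988226,FALSE
stratefy-global-v1,R,SLA,natural_log,NA,exponential_decay,-57.5924,62.6802,-0.0288,NA,NA,-11.3467682227961,12.45472337996156,TRUE
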