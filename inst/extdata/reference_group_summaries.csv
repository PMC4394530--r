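stratification,variable,group,n,mean,sd
response,age,nonresponder,16,43.0,17.8
response,age,responder,25,38.4,13.4
response,pre_n1,nonresponder,16,-0.37,0.53
response,pre_n1,responder,25,-0.41,0.53
response,pre_p2,nonresponder,16,0.58,0.40
response,pre_p2,responder,25,1.06,0.82
response,pre_n1p2,nonresponder,16,0.95,0.59
response,pre_n1p2,responder,25,1.47,0.83
response,post_n1,nonresponder,16,-0.44,0.35
response,post_n1,responder,25,-0.57,0.67
response,post_p2,nonresponder,16,0.63,0.73
response,post_p2,responder,25,0.90,0.95
response,post_n1p2,nonresponder,16,1.07,0.73
response,post_n1p2,responder,25,1.47,0.95
response,bdi_pre,nonresponder,16,28.9,9.8
response,bdi_pre,responder,25,32.4,13.8
response,bdi_post,nonresponder,16,25.6,9.5
response,bdi_post,responder,25,5.5,4.8
ldaep_split,age,low,20,44.2,14.6
ldaep_split,age,high,21,36.4,15.1
ldaep_split,pre_n1,low,20,-0.18,0.42
ldaep_split,pre_n1,high,21,-0.61,0.54
ldaep_split,pre_p2,low,20,0.44,0.44
ldaep_split,pre_p2,high,21,1.28,0.70
ldaep_split,pre_n1p2,low,20,0.62,0.36
ldaep_split,pre_n1p2,high,21,1.89,0.52
ldaep_split,post_n1,low,20,-0.35,0.58
ldaep_split,post_n1,high,21,-0.68,0.53
ldaep_split,post_p2,low,20,0.39,0.68
ldaep_split,post_p2,high,21,1.19,0.86
ldaep_split,post_n1p2,low,20,0.74,0.68
ldaep_split,post_n1p2,high,21,1.87,0.69
ldaep_split,bdi_pre,low,20,28.6,10.6
ldaep_split,bdi_pre,high,21,33.4,13.7
ldaep_split,bdi_post,low,20,17.9,13.0
ldaep_split,bdi_post,high,21,9.1,9.6
ldaep_split,bdi_change_pct,low,20,37.2,40.9
ldaep_split,bdi_change_pct,high,21,70.2,36.2
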