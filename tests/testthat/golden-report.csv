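block,group,measure,adaptation,value
detection,adult,accuracy,,99.7639
detection,adult,precision,,99.5924
detection,adult,recall,,97.7515
detection,adult,f1,,98.6217
detection,peer,accuracy,,99.8056
detection,peer,precision,,99.7863
detection,peer,recall,,95.8301
detection,peer,f1,,97.7508
measures,adult,tnu_mare,raw,2.63158
measures,adult,tnu_mre,raw,-3.4897
measures,adult,tnu_r,raw,0.997477
measures,adult,tnu_mare,adapted,7.03379
measures,adult,tnu_mre,adapted,1.54171
measures,adult,tnu_r,adapted,0.993121
measures,adult,tnw_mare,raw,23.9927
measures,adult,tnw_mre,raw,-25.2952
measures,adult,tnw_r,raw,0.995605
measures,adult,tnw_mare,adapted,7.49301
measures,adult,tnw_mre,adapted,2.33062
measures,adult,tnw_r,adapted,0.98952
measures,adult,ndw_mare,raw,4.55939
measures,adult,ndw_mre,raw,-5.14586
measures,adult,ndw_r,raw,0.987233
measures,adult,ndw_mare,adapted,12.2608
measures,adult,ndw_mre,adapted,2.45374
measures,adult,ndw_r,adapted,0.964633
measures,adult,mlu_mare,raw,22.6142
measures,adult,mlu_mre,raw,-22.6214
measures,adult,mlu_r,raw,0.859547
measures,adult,mlu_mare,adapted,5.15377
measures,adult,mlu_mre,adapted,-4.56269
measures,adult,mlu_r,adapted,0.744867
measures,adult,ttr_mare,raw,25.2951
measures,adult,ttr_mre,raw,26.9008
measures,adult,ttr_r,raw,0.989839
measures,adult,ttr_mare,adapted,7.64395
measures,adult,ttr_mre,adapted,-2.86696
measures,adult,ttr_r,adapted,0.95589
measures,peer,tnu_mare,raw,16.6667
measures,peer,tnu_mre,raw,-12.2222
measures,peer,tnu_r,raw,0.996124
measures,peer,tnu_mare,adapted,11.4266
measures,peer,tnu_mre,adapted,3.73162
measures,peer,tnu_r,adapted,0.987216
measures,peer,tnw_mare,raw,28.3019
measures,peer,tnw_mre,raw,-31.9411
measures,peer,tnw_r,raw,0.995928
measures,peer,tnw_mare,adapted,15.1397
measures,peer,tnw_mre,adapted,1.63189
measures,peer,tnw_r,adapted,0.991177
measures,peer,ndw_mare,raw,14.2857
measures,peer,ndw_mre,raw,-20.8333
measures,peer,ndw_r,raw,0.990747
measures,peer,ndw_mare,adapted,23.3019
measures,peer,ndw_mre,adapted,3.58789
measures,peer,ndw_r,adapted,0.975012
measures,peer,mlu_mare,raw,10.3774
measures,peer,mlu_mre,raw,-20.838
measures,peer,mlu_r,raw,0.463891
measures,peer,mlu_mare,adapted,NA
measures,peer,mlu_mre,adapted,NA
measures,peer,mlu_r,adapted,NA
measures,peer,ttr_mare,raw,15.7143
measures,peer,ttr_mre,raw,16.3377
measures,peer,ttr_r,raw,0.994675
measures,peer,ttr_mare,adapted,NA
measures,peer,ttr_mre,adapted,NA
measures,peer,ttr_r,adapted,NA
measures,focal,tnu_mare,raw,6.66667
measures,focal,tnu_mre,raw,-9.91667
measures,focal,tnu_r,raw,0.977326
measures,focal,tnu_mare,adapted,9.45861
measures,focal,tnu_mre,adapted,17.6804
measures,focal,tnu_r,adapted,0.902824
measures,focal,tnw_mare,raw,30.7692
measures,focal,tnw_mre,raw,-25.9006
measures,focal,tnw_r,raw,0.981529
measures,focal,tnw_mare,adapted,8.92686
measures,focal,tnw_mre,adapted,15.1638
measures,focal,tnw_r,adapted,0.913557
measures,focal,ndw_mare,raw,     10
measures,focal,ndw_mre,raw,-13.5509
measures,focal,ndw_r,raw,0.962107
measures,focal,ndw_mare,adapted,  15.89
measures,focal,ndw_mre,adapted,-30.2237
measures,focal,ndw_r,adapted,0.894383
measures,focal,mlu_mare,raw,     19
measures,focal,mlu_mre,raw,-17.9106
measures,focal,mlu_r,raw,0.806009
measures,focal,mlu_mare,adapted,7.05145
measures,focal,mlu_mre,adapted, 3.0676
measures,focal,mlu_r,adapted,0.652581
measures,focal,ttr_mare,raw,9.09091
measures,focal,ttr_mre,raw,18.5087
measures,focal,ttr_r,raw,-0.108334
measures,focal,ttr_mare,adapted,29.6238
measures,focal,ttr_mre,adapted,14.7227
measures,focal,ttr_r,adapted,-0.357115
interaction,adult,tdi_mre,,-1.83409
interaction,adult,tdi_mare,, 1.0153
interaction,adult,tdi_r,,0.999519
interaction,peer,tdi_mre,,-3.95807
interaction,peer,tdi_mare,,3.92097
interaction,peer,tdi_r,,0.999889
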