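segment,class,kappa_au,avg_t,max_t,avg_t2,max_t2,pca_t2
Happy1,Inconsistent,6,0,0,0,0,0
Happy1,Low Consistent,14,17,10,18,14,8
Happy1,Mild Consistent,6,13,44,18,44,43
Happy1,High Consistent,74,70,45,64,42,49
Happy2,Inconsistent,0,0,0,0,0,0
Happy2,Low Consistent,14,13,11,11,13,4
Happy2,Mild Consistent,60,56,70,59,63,74
Happy2,High Consistent,27,30,19,31,24,22
Surprise1,Inconsistent,0,0,0,0,0,0
Surprise1,Low Consistent,17,21,50,26,46,46
Surprise1,Mild Consistent,77,75,45,69,50,48
Surprise1,High Consistent,6,4,5,5,4,6
Fear,Inconsistent,0,0,1,0,0,0
Fear,Low Consistent,20,47,68,52,62,61
Fear,Mild Consistent,69,53,31,48,38,39
Fear,High Consistent,11,0,0,0,0,0
Disgust1,Inconsistent,1,0,0,0,0,0
Disgust1,Low Consistent,45,20,24,21,22,25
Disgust1,Mild Consistent,49,55,36,51,39,44
Disgust1,High Consistent,5,25,40,28,39,31
Disgust2,Inconsistent,1,0,0,0,0,0
Disgust2,Low Consistent,22,67,36,64,42,36
Disgust2,Mild Consistent,77,33,58,36,52,54
Disgust2,High Consistent,0,0,6,0,6,10
Sadness1,Inconsistent,89,67,68,68,66,68
Sadness1,Low Consistent,11,33,29,32,32,32
Sadness1,Mild Consistent,0,0,3,0,2,0
Sadness1,High Consistent,0,0,0,0,0,0
Sadness2,Inconsistent,100,74,79,74,75,78
Sadness2,Low Consistent,0,26,21,26,25,22
Sadness2,Mild Consistent,0,0,0,0,0,0
Sadness2,High Consistent,0,0,0,0,0,0
Surprise2,Inconsistent,33,49,44,48,49,44
Surprise2,Low Consistent,31,19,33,19,25,38
Surprise2,Mild Consistent,19,32,22,32,26,18
Surprise2,High Consistent,16,0,0,0,0,0
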