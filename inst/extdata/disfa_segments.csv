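name,start_frame,end_frame,emotion
Happy1,65,283,Happy
Happy2,343,755,Happy
Surprise1,817,1165,Surprise
Fear,1227,1354,Fear
Disgust1,1414,1874,Disgust
Disgust2,1935,2455,Disgust
Sadness1,2515,3200,Sadness
Sadness2,3261,3934,Sadness
Surprise2,3995,4832,Surprise
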