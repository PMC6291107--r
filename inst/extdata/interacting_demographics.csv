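species,sex,age,n
ALLEN,F,AHY,0
ALLEN,F,HY,0
ALLEN,F,UNKNOWN,1
ALLEN,M,AHY,3
ALLEN,M,HY,1
ALLEN,M,UNKNOWN,4
ANNA,F,AHY,10
ANNA,F,HY,14
ANNA,F,UNKNOWN,0
ANNA,M,AHY,18
ANNA,M,HY,17
ANNA,M,UNKNOWN,5
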