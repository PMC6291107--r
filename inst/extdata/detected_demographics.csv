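species,sex,age,n
ALLEN,F,AHY,3
ALLEN,F,HY,0
ALLEN,F,UNKNOWN,6
ALLEN,M,AHY,12
ALLEN,M,HY,1
ALLEN,M,UNKNOWN,12
ANNA,F,AHY,18
ANNA,F,HY,17
ANNA,F,UNKNOWN,6
ANNA,M,AHY,28
ANNA,M,HY,25
ANNA,M,UNKNOWN,13
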