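species,sex,age,n
ALLEN,F,AHY,6
ALLEN,F,HY,0
ALLEN,F,UNKNOWN,8
ALLEN,M,AHY,26
ALLEN,M,HY,2
ALLEN,M,UNKNOWN,21
ANNA,F,AHY,27
ANNA,F,HY,23
ANNA,F,UNKNOWN,18
ANNA,M,AHY,39
ANNA,M,HY,40
ANNA,M,UNKNOWN,20
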