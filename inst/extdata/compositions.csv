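composition,lipid,mol_percent
POPC,POPC,100
POPC/PI,POPC,30
POPC/PI,PI,20
POPC/PI-40,POPC,10
POPC/PI-40,PI,40
POPC/PIP,POPC,30
POPC/PIP,PIP,18
POPC/PIP2,POPC,30
POPC/PIP2,PIP2,12
POPC/PI/PIP,POPC,30
POPC/PI/PIP,PI,20
POPC/PI/PIP,PIP,18
POPC/PI/PIP2,POPC,30
POPC/PI/PIP2,PI,20
POPC/PI/PIP2,PIP2,12
MV1,POPC,30
MV1,PI,20
MV1,PIP,18
MV1,PIP2,12
MV2,POPC,30
MV2,Chol,20
MV2,POPE,25
MV2,POPS,5
MV2,PI,20
POPC/Chol,POPC,58
POPC/Chol,Chol,42
POPC/Chol/PI,POPC,28
POPC/Chol/PI,Chol,42
POPC/Chol/PI,PI,30
POPC/Chol/PI/PIP,POPC,28
POPC/Chol/PI/PIP,Chol,42
POPC/Chol/PI/PIP,PI,23
POPC/Chol/PI/PIP,PIP,7
POPC/Chol/PI/PIP2,POPC,28
POPC/Chol/PI/PIP2,Chol,42
POPC/Chol/PI/PIP2,PI,23
POPC/Chol/PI/PIP2,PIP2,7
NER,POPC,28
NER,Chol,42
NER,PI,16
NER,PIP,7
NER,PIP2,7
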