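# Axially symmetric 31P shielding anisotropies and isotropic shifts recovered
# from iterative lineshape simulation of each model-membrane composition.
# Line widths are synthetic defaults (not fitted quantities); delta_iso for
# PE and PS is a synthetic default (0.0 ppm).
composition,label,delta_sigma_ppm,delta_iso_ppm,linewidth_hz
POPC,PC,-47.0,-1.0,120
POPC/PI,PC,-40.0,-1.0,120
POPC/PI,PI_g,-61.0,-0.4,120
POPC/PIP,PC,-34.5,-1.0,120
POPC/PIP,PIP_g,-58.0,-0.3,120
POPC/PIP,PIP_4P,-14.0,1.5,120
POPC/PIP2,PC,-34.8,-1.0,120
POPC/PIP2,PIP2_g,-60.0,-0.4,120
POPC/PIP2,PIP2_4P,-14.0,1.0,120
POPC/PIP2,PIP2_5P,-6.0,0.2,120
MV1,PC,-32.0,-1.0,120
MV1,PI_g,-60.0,-0.4,120
MV1,PIP_g,-60.0,-0.3,120
MV1,PIP2_g,-60.0,-0.4,120
MV1,PIP_4P,-14.0,1.5,120
MV1,PIP2_4P,-14.0,1.0,120
MV1,PIP2_5P,-3.0,0.2,120
POPC/Chol,PC,-40.8,-1.0,120
POPC/Chol/PI,PC,-37.8,-1.0,120
POPC/Chol/PI,PI_g,-54.9,-0.4,120
NER,PC,-35.2,-1.0,120
NER,PI_g,-56.0,-0.4,120
NER,PIP_g,-56.0,-0.3,120
NER,PIP2_g,-56.0,-0.4,120
NER,PIP_4P,-11.5,1.5,120
NER,PIP2_4P,-11.5,1.0,120
NER,PIP2_5P,-3.0,0.2,120
MV2,PC,-38.0,-1.0,120
MV2,PE,-31.0,0.0,120
MV2,PS,-51.0,0.0,120
MV2,PI_g,-55.0,-0.4,120
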