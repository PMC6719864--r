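# Representative natural isotopic composition of tellurium and xenon.
# Source: CIAAW / NIST "Atomic Weights and Isotopic Compositions" compilation
# (representative isotopic composition column). Retrieved 2026-09-23.
# Fractional abundances; per element they sum to 1 within table rounding.
element,mass,abundance
Te,120,0.0009
Te,122,0.0255
Te,123,0.0089
Te,124,0.0474
Te,125,0.0707
Te,126,0.1884
Te,128,0.3174
Te,130,0.3408
Xe,124,0.000952
Xe,126,0.000890
Xe,128,0.019102
Xe,129,0.264006
Xe,130,0.040710
Xe,131,0.212324
Xe,132,0.269086
Xe,134,0.104357
Xe,136,0.088573
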