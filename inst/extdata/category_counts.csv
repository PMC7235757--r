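system,category,benign,malignant
eu,2,6,0
eu,3,17,1
eu,4,56,12
eu,5,19,22
acr,1,5,0
acr,2,23,2
acr,3,0,0
acr,4,48,16
acr,5,22,17
horvath,2,18,1
horvath,3,5,0
horvath,4A,38,6
horvath,4B,24,12
horvath,5,13,16
french,2,6,0
french,3,19,0
french,4A,56,3
french,4B,13,14
french,5,4,18
french4d,2,6,0
french4d,3,19,0
french4d,4A,49,2
french4d,4B,20,12
french4d,5,4,21
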