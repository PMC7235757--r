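system,category,low,high
eu,2,0,0
eu,3,0.02,0.04
eu,4,0.06,0.17
eu,5,0.26,0.87
acr,1,0.003,0.003
acr,2,0.015,0.015
acr,3,0.048,0.048
acr,4,0.091,0.091
acr,5,0.35,0.35
horvath,2,0,0
horvath,3,0,0.05
horvath,4A,0.05,0.10
horvath,4B,0.10,0.80
horvath,5,0.80,1
french,2,0,0
french,3,0.0025,0.0025
french,4A,0.06,0.06
french,4B,0.69,0.69
french,5,0.95,1
french4d,2,0,0
french4d,3,0.0025,0.0025
french4d,4A,0.06,0.06
french4d,4B,0.69,0.69
french4d,5,0.95,1
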