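parameter,region,method,scan,mean,sd
perfusion,whole,multi_ti,1,182.39,33.24
perfusion,whole,single_ti,1,215.47,32.84
perfusion,whole,multi_ti,2,194.70,30.68
perfusion,whole,single_ti,2,220.16,31.07
perfusion,cortex,multi_ti,1,184.84,32.88
perfusion,cortex,single_ti,1,220.20,31.72
perfusion,cortex,multi_ti,2,196.61,32.12
perfusion,cortex,single_ti,2,223.05,31.78
perfusion,medulla,multi_ti,1,168.49,37.87
perfusion,medulla,single_ti,1,179.16,37.39
perfusion,medulla,multi_ti,2,182.66,34.96
perfusion,medulla,single_ti,2,188.40,39.76
bat,whole,multi_ti,1,262.45,51.44
bat,whole,multi_ti,2,277.01,62.48
bat,cortex,multi_ti,1,290.77,70.07
bat,cortex,multi_ti,2,302.74,71.75
bat,medulla,multi_ti,1,184.21,37.93
bat,medulla,multi_ti,2,196.82,54.84
t1,whole,multi_ti,1,774.02,30.69
t1,whole,multi_ti,2,781.59,28.64
t1,cortex,multi_ti,1,786.17,31.33
t1,cortex,multi_ti,2,794.84,32.28
t1,medulla,multi_ti,1,799.32,38.25
t1,medulla,multi_ti,2,811.34,25.49
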