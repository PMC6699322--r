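slice,adc,slope,d,dstar,pf_percent
10,1.34,-0.29,0.743,9.21,26
11,1.24,-0.271,0.737,8.8,23
12,1.21,-0.258,0.732,8.57,22
13,1.2,-0.245,0.718,9.88,22
14,1.25,-0.243,0.741,10.18,23
15,1.29,-0.251,0.771,10.15,23
16,1.31,-0.253,0.778,10.09,24
17,1.26,-0.248,0.761,10.15,22
18,1.18,-0.242,0.734,10.15,20
19,1.15,-0.239,0.707,10.15,20
20,1.15,-0.239,0.68,10.13,21
21,1.22,-0.248,0.696,10.31,23
22,1.21,-0.252,0.702,10.05,23
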