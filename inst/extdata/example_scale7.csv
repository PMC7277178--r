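term,l,m,u
extremely low,0,0,1.5
very low,0.5,1.5,3
low,2,3,4.5
moderate,3.5,5,6.5
high,5.5,7,8
very high,7,8.5,9.5
extremely high,8.5,10,10
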