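feature_id,mz,s1,s2,s3
a,100.1234,1000,1200,900
b,102.1391,500,600,450
c,150.0500,2000,2400,1700
d,164.0657,1000,1150,900
e,300.2000,800,300,1500
f,451.3333,50,75,60
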