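province,Jiangsu,Zhejiang,Fujian,Guangdong,Guangxi
Jiangsu,0,,,,
Zhejiang,18.0646,0,,,
Fujian,15.157,3.4956,0,,
Guangdong,17.1004,9.4189,10.3014,0,
Guangxi,6.9854,14.7555,14.6588,11.9532,0
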