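table,b_nm,a_nm,eps_real,eps_imag
1,10,11,1.0092,3.2011
1,10,13,-2.5021,3.0123
1,10,15,-4.8721,2.6948
1,10,17,-6.4556,2.3952
1,10,20,-7.9297,2.0516
1,10,30,-9.7428,1.5407
1,10,40,-10.212,1.3921
1,10,100,-10.539,1.2845
2,10,11,1.0092,3.2011
2,12,13,1.3637,3.2017
2,14,15,1.6230,3.2000
2,16,17,1.8209,3.1975
2,18,19,1.9768,3.1947
2,20,21,2.1028,3.1921
2,100,101,3.0427,3.1587
3,9.5,10,2.04008,3.19339
3,9.0,10,0.77837,3.19889
3,8.5,10,-0.49070,3.16118
3,8.0,10,-1.74550,3.08115
3,7.5,10,-2.96636,2.96227
3,7.0,10,-4.13333,2.81043
3,6.5,10,-5.22780,2.63368
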