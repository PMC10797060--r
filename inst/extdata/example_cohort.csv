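id,AD,Depre,UTI,FNCNR,PCS,LiSAT,Age,Sex
1,present,absent,present,0,41.2,5,37,1
2,do_not_know,present,absent,1,28.9,2,52,0
3,absent,absent,present,0,35.0,4,44,1
4,present,present,do_not_know,1,30.6,3,61,1
5,absent,do_not_know,absent,0,38.4,6,29,0
6,present,absent,present,1,25.1,1,58,1
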