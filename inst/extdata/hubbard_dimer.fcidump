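&FCI NORB=2,NELEC=2,MS2=0,
 ORBSYM=1,1,
 ISYM=1,
/
4.0000000000000000E+00   1   1   1   1
4.0000000000000000E+00   2   2   2   2
-1.0000000000000000E+00   2   1   0   0
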