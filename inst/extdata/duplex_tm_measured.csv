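# Measured and nearest-neighbor-predicted melting temperatures (degrees C) of
# the replication-fork duplex constructs at three ionic conditions.
# Buffers: high_salt = 200 mM NaCl + 12 mM MgCl2; mid_salt = 100 mM + 6 mM;
# low_salt = 50 mM + 3 mM; all in 10 mM Tris pH 8.0. C_T = 500 nM.
construct,buffer,na_mm,mg_mm,tm_exp_c,tm_theory_c
unmodified,high_salt,200,12,69.6,69.6
unmodified,mid_salt,100,6,68.5,67.6
unmodified,low_salt,50,3,68.4,65.8
iCy3_iCy5,high_salt,200,12,66.8,68.9
iCy3_iCy5,mid_salt,100,6,65.8,67.0
iCy3_iCy5,low_salt,50,3,65.8,65.3
eCy3_eCy5,high_salt,200,12,63.1,70.0
eCy3_eCy5,mid_salt,100,6,62.0,68.3
eCy3_eCy5,low_salt,50,3,61.9,66.8
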