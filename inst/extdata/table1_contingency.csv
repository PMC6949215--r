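gene,snp_manual,mlpa,count,category
IKZF1,Normal,Normal,113,
IKZF1,Normal,Abnormal,1,iv
IKZF1,Abnormal,Normal,0,
IKZF1,Abnormal,Abnormal,21,
IKZF1,Abnormal,Abnormal,8,iii
ETV6,Normal,Normal,120,
ETV6,Normal,Abnormal,1,iv
ETV6,Abnormal,Normal,0,
ETV6,Abnormal,Abnormal,22,
CDKN2A,Normal,Normal,83,
CDKN2A,Normal,Abnormal,3,i
CDKN2A,Abnormal,Normal,0,
CDKN2A,Abnormal,Abnormal,57,
CDKN2B,Normal,Normal,83,
CDKN2B,Normal,Abnormal,2,ii
CDKN2B,Abnormal,Normal,0,
CDKN2B,Abnormal,Abnormal,58,
RB1,Normal,Normal,131,
RB1,Normal,Abnormal,2,iv
RB1,Abnormal,Normal,0,
RB1,Abnormal,Abnormal,10,
BTG1,Normal,Normal,142,
BTG1,Normal,Abnormal,0,
BTG1,Abnormal,Normal,0,
BTG1,Abnormal,Abnormal,1,
EBF1,Normal,Normal,133,
EBF1,Normal,Abnormal,0,
EBF1,Abnormal,Normal,1,v
EBF1,Abnormal,Abnormal,9,
PAX5,Normal,Normal,95,
PAX5,Normal,Abnormal,2,iv
PAX5,Abnormal,Normal,2,v
PAX5,Abnormal,Abnormal,43,
PAX5,Abnormal,Abnormal,1,iii
PAR1,Normal,Normal,138,
PAR1,Normal,Abnormal,2,i
PAR1,Abnormal,Normal,0,
PAR1,Abnormal,Abnormal,3,
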