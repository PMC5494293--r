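sample_id,group,set_id,age,gender,diagnosis,mean_pd_mm,bop
H1,healthy,set1,53,M,H,1.8,-
H2,healthy,set1,43,M,H,1.8,-
H3,healthy,set1,26,F,H,1.8,-
H4,healthy,set1,37,F,H,1.8,-
H5,healthy,set1,31,M,H,1.8,-
P1,periodontitis,set1,45,F,CP,2.8,+
P2,periodontitis,set1,70,F,CP,2.7,+/-
P3,periodontitis,set1,41,M,AgP,3.6,+
H6,healthy,set2,27,M,H,2.0,-
H7,healthy,set2,27,M,H,1.9,-
H8,healthy,set2,27,F,H,2.2,-
H9,healthy,set2,30,F,H,2.2,-
H10,healthy,set2,28,M,H,2.3,-
H11,healthy,set2,28,F,H,1.9,-
P4,periodontitis,set2,67,F,CP,2.5,+
P5,periodontitis,set2,34,F,AgP,3.1,+
P6,periodontitis,set2,73,M,CP,4.4,+
P7,periodontitis,set2,82,F,CP,2.3,+/-
P8,periodontitis,set2,68,F,CP,3.1,+
P9,periodontitis,set2,68,M,CP,2.3,+
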