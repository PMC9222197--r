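protein_id	gene	control_label	treated_label
Q8WVM0	TFB1M	unknown	mitochondrion
Q9Y3B7	MRPL11	unknown	mitochondrion
U3KQ69	MTG1	unknown	mitochondrion
Q969S9	GFM2	unknown	mitochondrion
Q96E29	MTERF3	unknown	mitochondrion
O75616	ERAL1	unknown	mitochondrion
Q4G0N4	NADK2	unknown	mitochondrion
Q5T440	IBA57	unknown	mitochondrion
Q96D53	COQ8B	unknown	mitochondrion
Q96DV4	MRPL38	unknown	mitochondrion
Q8TAE8	GADD45GIP1	unknown	mitochondrion
Q96HY7	DHTKD1	unknown	mitochondrion
P82933	MRPS9	unknown	mitochondrion
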