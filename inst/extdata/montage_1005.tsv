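label	x	y	z	region
Fp1	-0.30901699437494734	0.9510565162951536	6.123233995736766e-17	F
Fp2	0.30901699437494745	0.9510565162951535	6.123233995736766e-17	F
AF3	-0.37559486722749236	0.8848460565491465	0.27563735581699916	F
AF4	0.37559486722749263	0.8848460565491464	0.27563735581699916	F
F3	-0.5331784777634264	0.6824373310787412	0.5000000000000001	F
F4	0.5331784777634264	0.6824373310787412	0.5000000000000001	F
F7	-0.8090169943749473	0.5877852522924732	6.123233995736766e-17	F
F8	0.8090169943749475	0.5877852522924731	6.123233995736766e-17	F
Fz	4.329780281177466e-17	0.7071067811865475	0.7071067811865476	F
FC1	-0.2652642186070546	0.44147379642946344	0.8571673007021123	C
FC2	0.2652642186070547	0.4414737964294634	0.8571673007021123	C
FC5	-0.7646550456261504	0.4414737964294634	0.46947156278589086	C
FC6	0.7646550456261504	0.4414737964294634	0.46947156278589086	C
C3	-0.7071067811865475	8.659560562354932e-17	0.7071067811865476	C
C4	0.7071067811865475	0	0.7071067811865476	C
Cz	0	0	1	C
FT7	-0.9510565162951535	0.3090169943749475	6.123233995736766e-17	T
FT8	0.9510565162951535	0.3090169943749474	6.123233995736766e-17	T
T7	-1	1.2246467991473532e-16	6.123233995736766e-17	T
T8	1	0	6.123233995736766e-17	T
TP7	-0.9510565162951535	-0.30901699437494773	6.123233995736766e-17	T
TP8	0.9510565162951535	-0.3090169943749476	6.123233995736766e-17	T
CP1	-0.26526421860705474	-0.44147379642946333	0.8571673007021123	P
CP2	0.26526421860705457	-0.44147379642946344	0.8571673007021123	P
P3	-0.5331784777634262	-0.6824373310787413	0.5000000000000001	P
P4	0.5331784777634266	-0.6824373310787409	0.5000000000000001	P
P7	-0.8090169943749476	-0.587785252292473	6.123233995736766e-17	P
P8	0.8090169943749473	-0.5877852522924734	6.123233995736766e-17	P
Pz	-1.2989340843532398e-16	-0.7071067811865475	0.7071067811865476	P
PO3	-0.3755948672274925	-0.8848460565491464	0.27563735581699916	O
PO4	0.37559486722749225	-0.8848460565491466	0.27563735581699916	O
POz	-1.7032091095744818e-16	-0.9271838545667874	0.37460659341591196	O
O1	-0.30901699437494756	-0.9510565162951535	6.123233995736766e-17	O
O2	0.30901699437494723	-0.9510565162951536	6.123233995736766e-17	O
Oz	-1.8369701987210297e-16	-1	6.123233995736766e-17	O
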