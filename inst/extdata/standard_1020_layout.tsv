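name	x	y	z
Fp1	-0.293892626146237	0.904508497187474	0.309016994374947
Fp2	0.293892626146237	0.904508497187474	0.309016994374947
F3	-0.433027429173862	0.645416362854495	0.62922568617528
F4	0.433027429173862	0.645416362854495	0.62922568617528
C3	-0.587785252292473	3.59914663902998e-17	0.809016994374947
C4	0.587785252292473	3.59914663902998e-17	0.809016994374947
P3	-0.433027429173862	-0.645416362854495	0.62922568617528
P4	0.433027429173862	-0.645416362854494	0.62922568617528
O1	-0.293892626146237	-0.904508497187474	0.309016994374947
O2	0.293892626146237	-0.904508497187474	0.309016994374947
F7	-0.769420884293813	0.559016994374947	0.309016994374947
F8	0.769420884293813	0.559016994374947	0.309016994374947
T3	-0.951056516295154	5.82354159244546e-17	0.309016994374947
T4	0.951056516295154	5.82354159244546e-17	0.309016994374947
T5	-0.769420884293813	-0.559016994374947	0.309016994374947
T6	0.769420884293813	-0.559016994374947	0.309016994374947
Fz	0	0.587785252292473	0.809016994374947
Cz	0	0	1
Pz	7.19829327805997e-17	-0.587785252292473	0.809016994374947
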