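name	class	start	stop	strand
trnF	tRNA	137	207	+
rrnS	rRNA	208	1156	+
trnV	tRNA	1157	1222	+
rrnL	rRNA	1221	2785	+
trnL2	tRNA	2786	2860	+
nad1	PCG	2863	3813	+
trnI	tRNA	3818	3887	+
trnQ	tRNA	3885	3956	-
trnM	tRNA	3957	4024	+
nad2	PCG	4025	5062	+
trnW	tRNA	5067	5133	+
trnA	tRNA	5141	5209	-
trnN	tRNA	5211	5283	-
trnC	tRNA	5316	5381	-
trnY	tRNA	5382	5446	-
cox1	PCG	5448	6989	+
trnS2	tRNA	6990	7058	-
trnD	tRNA	7062	7130	+
cox2	PCG	7132	7791	+
trnK	tRNA	7860	7927	+
atp8	PCG	7929	8111	+
atp6	PCG	8090	8764	+
cox3	PCG	8770	9552	+
trnG	tRNA	9554	9620	+
nad3	PCG	9621	9965	+
trnR	tRNA	9967	10,031	+
nad4l	PCG	10,032	10,325	+
nad4	PCG	10,322	11,689	+
trnH	tRNA	11,700	11,768	+
trnS1	tRNA	11,769	11,827	+
trnL1	tRNA	11,828	11,898	+
nad5	PCG	11,902	13,701	+
nad6	PCG	13,717	14,235	-
trnE	tRNA	14,236	14,304	-
cob	PCG	14,309	15,442	+
trnT	tRNA	15,450	15,514	+
trnP	tRNA	15,517	15,583	-
control_region	control_region	15,584	136	+
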