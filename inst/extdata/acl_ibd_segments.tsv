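id1	id2	chrom	start	end	lod	cm
A_twin1	A_brother	chr2	3005297	3057952	5.34	3.944
A_twin1	A_twin2	chr2	3005007	3058005	6.37	3.945
A_twin1	A_twin2	chr15	22292484	22584320	5.94	3.59
A_twin1	A_twin2	chr21	16448783	16633125	10.67	2.077
A_father	A_brother	chr14	105952630	106208389	56.56	1.516
A_mother	A_brother	chr19	54184163	54537844	7.76	1.778
B_twin3	B_twin4	chr2	3009692	3047881	3.31	2.748
B_twin3	B_twin4	chr15	22370898	22524432	4.3	1.918
B_twin3	B_twin4	chr19	54529431	55093392	7.4	1.775
B_twin3	B_twin4	chr19	54539272	55088813	7.35	1.751
B_twin3	B_sister	chr13	111663671	111916421	4.31	1.551
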