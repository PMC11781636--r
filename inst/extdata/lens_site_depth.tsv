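sample	cg_site_num	cg_site_depth	cwg_site_num	cwg_site_depth
SL_1	851133	22.5	350184	8.71
SL_2	843258	21.36	371804	7.98
SL_3	836521	21.07	385816	7.76
SQ_1	837385	21.05	387132	7.91
SQ_2	832443	20.88	391180	7.81
SQ_3	826643	20.71	404810	7.67
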