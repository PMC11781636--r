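sample	raw	norm	adapter	enzyme	range	clean	percent
SL_1	83033801	61128449	60534408	34656532	31503675	30395078	49.72
SL_2	69481889	60936752	60308475	33432782	30130714	28994912	47.58
SL_3	96242834	61229760	60620405	32923888	29528455	28481767	46.52
SQ_1	65563461	61567057	60584303	31185676	28008463	26894267	43.68
SQ_2	73526131	60450114	59438500	30808513	27676897	26595900	44.00
SQ_3	80308732	60602711	59546888	30539711	27343383	26320986	43.43
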