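site_class	hyper	hypo	total
CCGG	27337	49187	76524
CCWGG	6327	9281	15608
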