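gene_id	rho	p	adj_p
SPAG5	0.5804	4.10e-05	0.000144479
SERPING1	0.3311	0.026795892	0.039512315
MYL9	0.5045	0.000486773	0.00119107
LMNB1	0.4149	0.004911333	0.008801109
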