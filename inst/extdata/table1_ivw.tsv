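exposure	outcome	printed_p	beta	ci_low	ci_high	q_pval	egger_intercept_p
morningness	SA_cuneus	0.004	32.63	10.35	54.90	0.14	0.69
morningness	TH_frontalpole	0.025	-0.04	-0.07	-0.005	0.76	0.70
morningness	SA_inferiorparietal	0.036	-77.69	-150.50	-4.89	0.11	0.86
morningness	SA_lateraloccipital	0.005	89.00	26.66	151.34	0.083	0.70
ease_of_getting_up	SA_lateralorbitofrontal	0.038	57.65	3.26	112.04	0.22	0.62
insomnia	TH_parahippocampal	0.037	0.002	0.0001	0.003	0.66	0.36
long_sleep	SA_isthmuscingulate	0.011	274.93	63.03	486.84	0.60	0.90
long_sleep	SA_parsopercularis	0.017	409.03	73.42	744.64	0.59	0.79
short_sleep	TH_frontalpole	0.019	-0.18	-0.33	-0.03	0.61	0.22
short_sleep	SA_inferiorparietal	0.025	-329.55	-618.55	-40.55	0.59	0.25
short_sleep	SA_lateraloccipital	0.007	394.37	107.89	680.85	0.34	0.73
short_sleep	SA_middletemporal	0.036	200.17	12.97	387.37	0.71	0.38
short_sleep	TH_middletemporal	0.002	0.12	0.05	0.20	0.31	0.76
short_sleep	TH_paracentral	0.006	-0.11	-0.19	-0.03	0.69	0.84
short_sleep	TH_parahippocampal	0.006	-0.25	-0.42	-0.07	0.81	0.81
short_sleep	TH_superiortemporal	0.013	0.09	0.02	0.16	0.42	0.47
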