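sample_id	ecosystem_type	ecosystem	gc_content	gene_count	pct_ko_annotated	has_copy_data	is_combined_assembly	use_restricted	true_cluster
S0001	Soil-like	Environmental	0.66545609096496	411019	40.3	TRUE	FALSE	FALSE	1
S0002	Soil-like	Environmental	0.65008224263337	234731	40.2	TRUE	FALSE	FALSE	1
S0003	Soil-like	Environmental	0.640304228745467	377173	36.3	TRUE	FALSE	FALSE	1
S0004	Soil-like	Environmental	0.535307083343841	383404	39.2	TRUE	FALSE	FALSE	1
S0005	Soil-like	Environmental	0.612343117306891	222269	44	TRUE	FALSE	FALSE	1
S0006	Soil-like	Environmental	0.618523402198117	386625	42.9	TRUE	FALSE	FALSE	1
S0007	Soil-like	Environmental	0.605712670340364	467669	40.3	TRUE	FALSE	FALSE	1
S0008	Soil-like	Environmental	0.603592633634951	307750	35.6	TRUE	FALSE	FALSE	1
S0009	Soil-like	Environmental	0.5799463580457	433416	43.9	TRUE	FALSE	FALSE	1
S0010	Soil-like	Environmental	0.609229013444572	361123	37	TRUE	FALSE	FALSE	1
S0011	Soil-like	Environmental	0.567853508123435	473564	40.7	TRUE	FALSE	FALSE	1
S0012	Soil-like	Environmental	0.610309494932191	361648	43.6	TRUE	FALSE	FALSE	1
S0013	Aquatic-like	Environmental	0.490233554844604	388401	39.4	TRUE	FALSE	FALSE	2
S0014	Aquatic-like	Environmental	0.455775902988102	381742	41	TRUE	FALSE	FALSE	2
S0015	Aquatic-like	Environmental	0.420731519673965	403972	43.6	TRUE	FALSE	FALSE	2
S0016	Aquatic-like	Environmental	0.448172366462204	470076	41.3	TRUE	FALSE	FALSE	2
S0017	Aquatic-like	Environmental	0.499791700668681	269324	38	TRUE	FALSE	FALSE	2
S0018	Aquatic-like	Environmental	0.447779655942758	453479	40.4	TRUE	FALSE	FALSE	2
S0019	Aquatic-like	Environmental	0.46176318514149	292512	35.2	TRUE	FALSE	FALSE	2
S0020	Aquatic-like	Environmental	0.511555322953203	493343	36.1	TRUE	FALSE	FALSE	2
S0021	Aquatic-like	Environmental	0.456254825658955	173302	39.1	TRUE	FALSE	FALSE	2
S0022	Aquatic-like	Environmental	0.493215698104462	494068	35.4	TRUE	FALSE	FALSE	2
S0023	Aquatic-like	Environmental	0.43321582776143	315279	38.4	TRUE	FALSE	FALSE	2
S0024	Aquatic-like	Environmental	0.43613943460756	295701	35.5	TRUE	FALSE	FALSE	2
S0025	Anaerobic-like	Environmental	0.412295983514659	192380	40.5	TRUE	FALSE	FALSE	3
S0026	Anaerobic-like	Environmental	0.504941119577836	340395	42.7	TRUE	FALSE	FALSE	3
S0027	Anaerobic-like	Environmental	0.412961830005656	313259	41.7	TRUE	FALSE	FALSE	3
S0028	Anaerobic-like	Environmental	0.478592197282786	204410	39.8	TRUE	FALSE	FALSE	3
S0029	Anaerobic-like	Environmental	0.447748870187001	427173	42.8	TRUE	FALSE	FALSE	3
S0030	Anaerobic-like	Environmental	0.432525860792313	163958	39.8	TRUE	FALSE	FALSE	3
S0031	Anaerobic-like	Environmental	0.477297822914388	415242	39.7	TRUE	FALSE	FALSE	3
S0032	Anaerobic-like	Environmental	0.503856166683703	447488	43.2	TRUE	FALSE	FALSE	3
S0033	Anaerobic-like	Environmental	0.409041768030843	438597	39.7	TRUE	FALSE	FALSE	3
S0034	Anaerobic-like	Environmental	0.45186542633381	376516	43.8	TRUE	FALSE	FALSE	3
S0035	Anaerobic-like	Environmental	0.427787081410154	340207	37.4	TRUE	FALSE	FALSE	3
S0036	Anaerobic-like	Environmental	0.449304378551221	499852	35.9	TRUE	FALSE	FALSE	3
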