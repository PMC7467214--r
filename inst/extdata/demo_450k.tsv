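probe_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010
P000001	0.3257	0.0151	0.341	0.3505	0.4454	0.3662	0.1164	0.2712	0.2289	0.209
P000002	0.532	0.2388	0.3463	0.1626	0.1811	0.0903	0.1311	0.1081	0.1922	0.1792
P000003	0.336	0.7006	0.2639	0.6105	0.7431	0.3588	0.3693	0.33	0.6649	0.5315
P000004	0.2226	0.0722	0.359	0.2786	0.392	0.15	0.2319	0.1201	0.1557	0.1528
P000005	0.1039	0.2417	0.1657	0.1242	0.131	0.2293	0.2426	0.1023	0.4263	0.1469
P000006	0.9318	0.8994	0.939	0.9554	0.8033	0.9233	0.733	0.8702	0.9214	0.9456
P000007	0.6364	0.7337	0.7841	0.815	0.7543	0.754	0.8325	0.4754	0.7112	0.7438
P000008	0.8525	0.8704	0.8321	0.8592	0.9284	0.8996	0.8223	0.956	0.9297	0.9698
P000009	0.9081	0.8128	0.8852	0.8422	0.8325	0.7699	0.8934	0.9273	0.8393	0.8084
P000010	0.976	0.9238	0.8051	0.8025	0.8482	0.7021	0.7741	0.948	0.8592	0.9573
P000011	0.95	0.8162	0.9164	0.9381	0.9343	0.8295	0.931	0.9373	0.9252	0.8709
P000012	0.4808	0.5153	0.6932	0.6862	0.6658	0.5653	0.5697	0.7041	0.5653	0.6561
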