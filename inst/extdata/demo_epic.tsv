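probe_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010
P000001	0.3058	0.0316	0.3637	0.4512	0.3159	0.332	0.2189	0.1885	0.3195	0.2689
P000002	0.3473	0.2577	0.2618	0.2054	0.1848	0.1089	0.07	0.1018	0.2048	0.1367
P000003	0.2618	0.661	0.4321	0.4078	0.7329	0.4058	0.4756	0.2396	0.4423	0.414
P000004	0.167	0.1114	0.1332	0.2371	0.3813	0.1214	0.456	0.1956	0.4418	0.1584
P000005	0.4168	0.2463	0.2674	0.1184	0.1738	0.107	0.1189	0.0695	0.186	0.0827
P000006	0.9634	0.8456	0.9328	0.9521	0.8584	0.7999	0.9307	0.9277	0.9018	0.8754
P000007	0.7568	0.7691	0.8198	0.6613	0.8557	0.6955	0.8663	0.6225	0.7837	0.7346
P000008	0.9711	0.8289	0.9237	0.9616	0.8857	0.9409	0.9676	0.6867	0.8394	0.9609
P000009	0.8481	0.9165	0.8836	0.8852	0.9424	0.7877	0.8868	0.9155	0.8787	0.7864
P000010	0.7532	0.8847	0.9702	0.9225	0.8223	0.8777	0.9407	0.7855	0.8767	0.8732
P000011	0.9023	0.8722	0.922	0.9058	0.9092	0.9344	0.8784	0.9492	0.9516	0.8964
P000012	0.5881	0.5363	0.6369	0.6784	0.6916	0.6499	0.5229	0.6526	0.5082	0.5792
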