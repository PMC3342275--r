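construct	n_embryos	anatomy	proportion	p_prop	p_ranksum	fold
control	161	Forebrain	0.3354	NA	NA	NA
control	161	Midbrain/Hindbrain	0.2546	NA	NA	NA
control	161	Eye	0.1800	NA	NA	NA
control	161	Ear/AboveHeart	0.0680	NA	NA	NA
control	161	Heart	0.3160	NA	NA	NA
control	161	Notochord	0.1610	NA	NA	NA
control	161	Yolk/YolkExtension	0.1550	NA	NA	NA
control	161	MidTrunk/AboveYolk	0.0800	NA	NA	NA
control	161	Muscle	0.1800	NA	NA	NA
control	161	TailRegion	0.1240	NA	NA	NA
CCE-rab11fip4a	53	Forebrain	0.4340	0.1289	0.1964	NA
CCE-rab11fip4a	53	Midbrain/Hindbrain	0.1509	0.9147	0.9497	NA
CCE-rab11fip4a	53	Eye	0.2264	0.2941	0.2282	NA
CCE-rab11fip4a	53	Ear/AboveHeart	0.0189	0.8445	0.9744	NA
CCE-rab11fip4a	53	Heart	0.2264	0.8595	0.9047	NA
CCE-rab11fip4a	53	Notochord	0.6038	5.14e-10	0.0058	3.8
CCE-rab11fip4a	53	Yolk/YolkExtension	0.2075	0.2512	0.2801	NA
CCE-rab11fip4a	53	MidTrunk/AboveYolk	0.0943	0.4904	0.5277	NA
CCE-rab11fip4a	53	Muscle	0.1509	0.6094	0.7513	NA
CCE-rab11fip4a	53	TailRegion	0.1887	0.1725	0.4191	NA
CCE-abca1a	43	Forebrain	0.3488	0.5000	0.5680	NA
CCE-abca1a	43	Midbrain/Hindbrain	0.3953	0.0519	0.1371	NA
CCE-abca1a	43	Eye	0.4419	0.0003	0.0460	2.5
CCE-abca1a	43	Ear/AboveHeart	0.0698	0.5000	0.7036	NA
CCE-abca1a	43	Heart	0.0000	1.0000	0.9981	NA
CCE-abca1a	43	Notochord	0.3953	0.0009	0.0057	2.5
CCE-abca1a	43	Yolk/YolkExtension	0.3953	0.0006	0.0276	2.6
CCE-abca1a	43	MidTrunk/AboveYolk	0.0930	0.5000	0.5800	NA
CCE-abca1a	43	Muscle	0.3488	0.0146	0.0524	NA
CCE-abca1a	43	TailRegion	0.1163	0.5000	0.5419	NA
CCE-odz3	39	Forebrain	0.8205	5.48e-08	0.0053	2.4
CCE-odz3	39	Midbrain/Hindbrain	0.0256	0.9983	0.9961	NA
CCE-odz3	39	Eye	0.0769	0.9089	0.9572	NA
CCE-odz3	39	Ear/AboveHeart	0.2821	0.0002	0.0287	4.1
CCE-odz3	39	Heart	0.1538	0.9660	0.9758	NA
CCE-odz3	39	Notochord	0.0769	0.8627	0.9847	NA
CCE-odz3	39	Yolk/YolkExtension	0.1282	0.5694	0.7832	NA
CCE-odz3	39	MidTrunk/AboveYolk	0.1538	0.1373	0.2014	NA
CCE-odz3	39	Muscle	0.5128	1.84e-05	0.0205	2.8
CCE-odz3	39	TailRegion	0.2051	0.1470	0.1681	NA
CCE-rfx2	48	Forebrain	0.3750	0.3693	0.5038	NA
CCE-rfx2	48	Midbrain/Hindbrain	0.1250	0.9546	0.9711	NA
CCE-rfx2	48	Eye	0.1667	0.5000	0.7784	NA
CCE-rfx2	48	Ear/AboveHeart	0.0208	0.8127	0.9525	NA
CCE-rfx2	48	Heart	0.1042	0.9969	0.9950	NA
CCE-rfx2	48	Notochord	0.1042	0.7732	0.8387	NA
CCE-rfx2	48	Yolk/YolkExtension	0.2708	0.0539	0.1060	NA
CCE-rfx2	48	MidTrunk/AboveYolk	0.0000	0.9547	0.9966	NA
CCE-rfx2	48	Muscle	0.6875	2.44e-11	0.0051	3.8
CCE-rfx2	48	TailRegion	0.1667	0.3028	0.2205	NA
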