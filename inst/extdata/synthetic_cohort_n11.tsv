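id	sex	age_at_surgery	height_cm	weight_kg	bmi_pre	weight_loss_12m_kg	bmi_post	charge_preoperative_Clinic	charge_preoperative_Ancillary	charge_preoperative_Diagnostic	charge_perioperative_Ancillary	charge_perioperative_Diagnostic	charge_perioperative_Gen_nursing	charge_perioperative_Minimally_invasive_procedures	charge_perioperative_Pharmacy	charge_perioperative_Surgery_and_procedures	charge_foundation_Surgical_foundation	charge_postoperative_Clinic	charge_postoperative_Ancillary	charge_postoperative_Surgery_and_procedures	total_charges
1	F	16.13832138	153.0747589	159.5621043	68.0961544	33.99868707	53.58656984	307.5869378	91.17347611	1757.804095	291.4583882	499.3636646	6450.576836	49.31883035	3230.69209	32893.73436	3395.945736	894.6397498	828.6413701	245.4996599	50936.43519
2	M	19.12076824	175.9261036	141.9540755	45.86562304	38.59741873	33.39472602	448.9465356	238.5705666	3018.910863	202.3729148	1231.458379	8463.779055	7.945320136	2801.311447	23801.18911	3895.814566	24.39550388	704.7657563	689.2165745	45528.67659
3	F	18.2663684	175.7408694	126.3972411	40.92531713	25.43958728	32.68840335	564.732636	132.9468798	836.8801754	62.47148824	298.3233556	7485.873157	20.60043929	3622.287204	33359.23749	3313.12576	283.2116112	1493.204889	416.7490026	51889.64409
4	F	19.96065791	166.6649428	90.70276063	32.6536693	30.69276688	21.60404465	434.9145714	268.3242888	2033.770573	340.3255445	522.4899472	5129.872271	79.27551211	2967.886654	26884.86065	4158.228952	686.3733868	2256.030057	995.1822993	46757.53471
5	F	16.55050029	168.6287716	156.8231129	55.15015248	57.11443313	35.06465847	391.0215818	216.4253746	991.95581	366.1396285	1682.210341	9153.874128	12.90960169	2891.673547	31817.91903	4348.443086	65.13770016	220.4002831	68.42074556	52226.53086
6	F	14.41912327	161.8508449	147.4375435	56.28311746	46.1509787	38.66534594	335.0052407	107.3578721	2583.032702	148.2723688	1225.892458	5818.764909	33.78541426	3890.005247	30759.40956	2942.074854	492.3933772	421.6270266	770.1571704	49527.7782
7	M	18.79188727	176.1828713	146.8317132	47.30341544	37.61997266	35.18373668	160.6042915	196.8412985	1016.445421	304.0434939	808.7899177	4915.477965	1.340249717	3078.760394	31745.71331	2938.056863	567.1450134	2677.108752	682.2645277	49092.5915
8	F	17.14366882	174.4276602	139.898386	45.98137918	43.27393567	31.75823264	398.6300919	10.36009262	1040.710262	519.2779354	1279.093869	6288.368144	40.42229084	3340.769644	29645.78673	3331.745681	507.9406313	2538.072793	413.0290325	49354.2072
9	M	18.06154962	164.9273451	141.2984871	51.94600768	20.74098868	44.32093271	538.5460134	251.6601126	1359.778051	92.18986224	758.9868372	6878.458093	18.79315507	3812.567496	26550.43396	3700.569439	98.33531932	2551.939718	1126.913045	47739.1711
10	F	17.12614236	169.7995165	139.3440234	48.32985007	41.34894695	33.98844986	131.3642691	265.8823423	244.3334501	326.1831382	949.7418722	6295.325584	14.75169793	3633.216424	28275.04255	3316.563423	729.122063	3821.140993	330.8166489	48333.48446
11	F	18.75560891	160.7725641	137.7426235	53.28984706	36.77798863	39.06118392	133.8396939	220.3596186	408.3395253	366.1532887	1415.845471	4546.622799	64.16824969	3888.4743	25046.86512	4125.073133	592.3911948	2007.542308	111.7106887	42927.38539
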