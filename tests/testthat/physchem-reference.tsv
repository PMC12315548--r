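sequence	molecular_weight	aromaticity	instability_index	isoelectric_point	gravy	net_charge_ph7
FQAEMDTHEPGPKDSCGPAFILQIRQMMWMQMRSHLCQPLMPQCEQAKVKEVACFSWLYCHSHMATAQDCTPVTIPWGNIPQGEECWHQEAFINGCKSIRPAVNLQNQNPYQIPY	13253.144699999986	0.09565217391304348	66.37913043478261	5.8955904006958	-0.44173913043478247	-2.867222855390846
RINNIWALKLYPANVYHESDMFGDPNWLPQSMPVFDKVRFKYGGCMQEGQYKNSNRFKDPTGYH	7601.510300000003	0.171875	43.67343749999999	8.834441184997559	-0.8953125000000001	1.924632958615252
ITNMIKCNCWHYWQYYDCQDNDWQCLRFVQLLYELYHSGCPYATKACWENCRYHCFIKHINYGKTTEDITQDHWLKHENWMGWGSTQCMVLIDHISYDY	12262.747199999993	0.1919191919191919	51.625252525252506	5.905991935729981	-0.6101010101010099	-3.7147058192329414
WHVLNFVWKGHPAGWLCTNKFCMHMAHDGEAIERHWQFDNGHQSQQYNSCNMAFILKWWDNFVIWNLIDQCYFNETLPMCRGGATDYVLGHNWAGLYSCYAGI	12161.65269999999	0.18446601941747573	47.99029126213591	6.119877052307127	-0.2640776699029124	-2.6830618257958037
RPTMVSSHISENIVQHTCMEDTLFILFDYMYDPMILWKHGAARDGGFHISMKGFLEAFWSILNITKFKCMNSFG	8607.959499999994	0.14864864864864866	68.57567567567568	6.435390281677246	0.09729729729729722	-0.9041031891053679
ETWEASMFEVHNKYNMCRDGMYLNITKFPTDAAVSEDNGPGVFQEPY	5433.946200000003	0.14893617021276595	48.34468085106382	4.32910785675049	-0.6936170212765957	-5.0763000573290595
FPLTFGHAIRRKGDHEAWMWWINKWSPYEMSHNKLQPYHVASPPDEFKRIRTRTPPNSHEERNYWHWDIKWDICERLWMFRT	10379.6556	0.18292682926829268	70.59634146341462	9.301836967468262	-1.139024390243903	3.2865195620244414
NVFEEWCSKPDNFTAKYAHIPRGTWLANYWMYDSHKLSGFVQVMAAGGTELMHCYGIEKTPAEQDLVQTPDHKWQILLHKNYMDGKIETGAPNPWRSPDEQSFIYLEQMWKNG	13195.735599999993	0.1415929203539823	59.09911504424778	5.655331993103027	-0.697345132743363	-3.8086271770970495
GAEVNFTTQCDIVRPPDCDHRSTQYQKLPGFFLVSVLG	4239.7432	0.10526315789473684	26.063157894736843	5.428828620910643	-0.18947368421052627	-1.1683714347593899
QITAMQIFYLDDMTSSISQLLRYEPGRDVWTCTVWWECCIRCIGAGNELMPRMKTRMTQNRYQWRVRFAIKQKMNVMERYENSKQVVANCDSLLDEPMSL	11952.809799999994	0.1	38.6181	8.363821983337402	-0.4109999999999999	1.7249812331407224
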