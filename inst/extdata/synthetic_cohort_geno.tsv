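subject_id	rs100001	rs100002	rs100003	rs100004	rs100005	rs100006	rs100007	rs100008
S00001	2	1	0	2	0	1	0	1
S00002	1	2	0	2	1	1	1	0
S00003	1	2	1	1	0	1	0	0
S00004	0	0	0	1	0	2	2	0
S00005	1	1	1	0	1	1	0	0
S00006	0	1	0	2	2	0	1	0
S00007	1	1	1	0	1	0	1	0
S00008	1	1	1	0	0	1	0	0
S00009	1	0	0	2	0	1	0	1
S00010	1	1	0	2	1	2	1	0
S00011	1	1	0	1	1	1	0	1
S00012	2	2	0	2	0	1	1	0
S00013	1	1	1	1	1	1	0	0
S00014	0	0	0	2	1	0	0	0
S00015	1	1	0	0	1	0	1	0
S00016	1	1	1	0	1	1	0	0
S00017	1	1	1	1	1	1	0	0
S00018	1	1	1	0	0	0	1	0
S00019	0	0	0	2	0	0	0	0
S00020	2	1	1	1	1	1	0	0
S00021	1	1	1	0	1	0	1	0
S00022	0	0	0	1	1	0	0	0
S00023	0	0	0	0	1	0	0	2
S00024	0	0	0	1	1	1	0	0
S00025	1	0	0	2	1	0	2	0
S00026	1	1	1	2	1	1	0	0
S00027	2	2	1	2	0	0	0	0
S00028	0	1	0	1	1	0	0	0
S00029	1	1	1	0	0	1	1	0
S00030	1	0	0	1	1	2	0	0
S00031	2	2	1	2	1	1	2	0
S00032	1	1	1	1	1	1	1	1
S00033	0	0	0	0	1	0	0	0
S00034	0	0	0	1	0	0	0	1
S00035	1	1	1	1	1	0	1	0
S00036	1	1	0	0	1	0	1	1
S00037	1	2	1	1	0	2	1	0
S00038	0	0	0	2	2	0	1	0
S00039	1	2	1	2	2	0	1	0
S00040	1	1	0	1	0	1	0	0
S00041	1	1	1	1	0	0	0	0
S00042	2	2	1	1	0	1	1	0
S00043	0	0	0	0	0	2	0	0
S00044	1	1	1	0	1	1	0	0
S00045	1	0	0	1	1	0	1	0
S00046	1	1	0	2	0	0	1	0
S00047	1	0	0	0	0	0	0	0
S00048	0	0	0	1	0	0	1	0
S00049	1	1	0	1	0	1	1	0
S00050	2	2	1	1	1	1	1	0
S00051	1	0	0	2	0	1	0	0
S00052	1	0	0	0	0	1	0	0
S00053	0	1	0	1	1	1	0	0
S00054	1	1	0	0	1	1	0	0
S00055	1	1	1	0	1	0	0	0
S00056	1	0	0	1	1	0	0	0
S00057	0	0	0	1	0	2	1	0
S00058	0	1	0	0	2	0	1	0
S00059	2	1	0	1	0	2	1	0
S00060	2	2	2	1	1	0	1	0
S00061	1	1	1	0	0	0	2	0
S00062	2	2	1	1	0	0	0	0
S00063	2	2	0	0	0	1	0	0
S00064	1	1	1	2	0	0	0	0
S00065	1	1	0	0	1	1	0	0
S00066	1	2	0	1	0	1	1	0
S00067	0	0	0	0	0	0	0	0
S00068	1	1	0	0	1	1	0	1
S00069	1	1	0	0	1	0	2	0
S00070	1	1	1	1	2	0	1	0
S00071	1	1	1	1	1	0	1	0
S00072	1	1	0	1	0	1	0	0
S00073	2	2	1	1	1	0	0	0
S00074	1	1	0	0	0	1	1	0
S00075	1	1	0	1	1	1	1	0
S00076	0	0	0	1	0	2	0	0
S00077	2	2	2	1	2	1	1	0
S00078	1	2	0	0	0	0	0	1
S00079	2	1	0	0	1	1	0	0
S00080	1	0	0	1	2	0	0	0
S00081	0	0	0	2	1	0	0	0
S00082	1	1	0	1	0	1	1	0
S00083	1	1	0	1	0	1	0	0
S00084	0	0	0	0	1	1	0	0
S00085	1	1	0	0	0	1	1	0
S00086	1	1	0	1	2	0	1	0
S00087	1	1	0	0	0	1	0	0
S00088	0	1	0	1	0	0	1	0
S00089	1	1	0	0	0	1	1	0
S00090	1	1	1	1	1	0	0	1
S00091	0	0	0	2	0	0	0	0
S00092	1	1	0	1	1	1	2	0
S00093	1	1	1	2	0	0	1	0
S00094	0	1	0	2	1	1	1	0
S00095	0	0	1	0	1	0	0	1
S00096	2	2	0	1	1	2	1	1
S00097	1	1	1	1	1	0	2	0
S00098	1	1	1	1	1	1	0	0
S00099	0	0	0	1	1	2	0	0
S00100	1	1	1	0	0	1	1	0
S00101	0	1	0	0	0	0	1	1
S00102	0	0	0	1	0	0	1	0
S00103	1	1	0	0	0	1	1	0
S00104	0	0	0	1	0	0	1	0
S00105	0	1	0	1	0	0	1	1
S00106	1	1	0	0	1	0	0	0
S00107	0	1	0	2	1	1	0	1
S00108	2	1	0	0	1	1	0	0
S00109	1	1	0	0	1	2	1	0
S00110	0	0	0	1	1	0	0	0
S00111	0	0	0	0	1	0	2	0
S00112	0	0	0	1	1	0	1	0
S00113	0	0	0	0	0	0	0	0
S00114	2	2	2	1	0	1	2	0
S00115	0	0	0	0	0	1	2	0
S00116	1	1	1	1	0	1	1	1
S00117	0	0	0	2	0	0	1	0
S00118	1	0	0	0	0	1	1	0
S00119	2	1	0	0	0	0	1	0
S00120	1	1	0	0	0	1	0	1
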