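# contact potentials (synthetic hydrophobicity-derived); aa order: ACDEFGHIKLMNPQRSTVWY
aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-3.09	-3.3156	-1.3822	-1.3822	-3.4122	-2.3811	-1.4789	-3.96	-1.2533	-3.7344	-3.1222	-1.3822	-1.9944	-1.3822	-1.06	-2.2522	-2.2844	-3.8633	-2.22	-2.0911
C	-3.3156	-3.5593	-1.4704	-1.4704	-3.6637	-2.5496	-1.5748	-4.2556	-1.3311	-4.0119	-3.3504	-1.4704	-2.1319	-1.4704	-1.1222	-2.4104	-2.4452	-4.1511	-2.3756	-2.2363
D	-1.3822	-1.4704	-0.7148	-0.7148	-1.5081	-1.1052	-0.7526	-1.7222	-0.6644	-1.6341	-1.3948	-0.7148	-0.9541	-0.7148	-0.5889	-1.0548	-1.0674	-1.6844	-1.0422	-0.9919
E	-1.3822	-1.4704	-0.7148	-0.7148	-1.5081	-1.1052	-0.7526	-1.7222	-0.6644	-1.6341	-1.3948	-0.7148	-0.9541	-0.7148	-0.5889	-1.0548	-1.0674	-1.6844	-1.0422	-0.9919
F	-3.4122	-3.6637	-1.5081	-1.5081	-3.7715	-2.6219	-1.6159	-4.3822	-1.3644	-4.1307	-3.4481	-1.5081	-2.1907	-1.5081	-1.1489	-2.4781	-2.5141	-4.2744	-2.4422	-2.2985
G	-2.3811	-2.5496	-1.1052	-1.1052	-2.6219	-1.8515	-1.1774	-3.0311	-1.0089	-2.8626	-2.4052	-1.1052	-1.5626	-1.1052	-0.8644	-1.7552	-1.7793	-2.9589	-1.7311	-1.6348
H	-1.4789	-1.5748	-0.7526	-0.7526	-1.6159	-1.1774	-0.7937	-1.8489	-0.6978	-1.753	-1.4926	-0.7526	-1.013	-0.7526	-0.6156	-1.1226	-1.1363	-1.8078	-1.1089	-1.0541
I	-3.96	-4.2556	-1.7222	-1.7222	-4.3822	-3.0311	-1.8489	-5.1	-1.5533	-4.8044	-4.0022	-1.7222	-2.5244	-1.7222	-1.3	-2.8622	-2.9044	-4.9733	-2.82	-2.6511
K	-1.2533	-1.3311	-0.6644	-0.6644	-1.3644	-1.0089	-0.6978	-1.5533	-0.62	-1.4756	-1.2644	-0.6644	-0.8756	-0.6644	-0.5533	-0.9644	-0.9756	-1.52	-0.9533	-0.9089
L	-3.7344	-4.0119	-1.6341	-1.6341	-4.1307	-2.8626	-1.753	-4.8044	-1.4756	-4.527	-3.7741	-1.6341	-2.387	-1.6341	-1.2378	-2.7041	-2.7437	-4.6856	-2.6644	-2.5059
M	-3.1222	-3.3504	-1.3948	-1.3948	-3.4481	-2.4052	-1.4926	-4.0022	-1.2644	-3.7741	-3.1548	-1.3948	-2.0141	-1.3948	-1.0689	-2.2748	-2.3074	-3.9044	-2.2422	-2.1119
N	-1.3822	-1.4704	-0.7148	-0.7148	-1.5081	-1.1052	-0.7526	-1.7222	-0.6644	-1.6341	-1.3948	-0.7148	-0.9541	-0.7148	-0.5889	-1.0548	-1.0674	-1.6844	-1.0422	-0.9919
P	-1.9944	-2.1319	-0.9541	-0.9541	-2.1907	-1.5626	-1.013	-2.5244	-0.8756	-2.387	-2.0141	-0.9541	-1.327	-0.9541	-0.7578	-1.4841	-1.5037	-2.4656	-1.4644	-1.3859
Q	-1.3822	-1.4704	-0.7148	-0.7148	-1.5081	-1.1052	-0.7526	-1.7222	-0.6644	-1.6341	-1.3948	-0.7148	-0.9541	-0.7148	-0.5889	-1.0548	-1.0674	-1.6844	-1.0422	-0.9919
R	-1.06	-1.1222	-0.5889	-0.5889	-1.1489	-0.8644	-0.6156	-1.3	-0.5533	-1.2378	-1.0689	-0.5889	-0.7578	-0.5889	-0.5	-0.8289	-0.8378	-1.2733	-0.82	-0.7844
S	-2.2522	-2.4104	-1.0548	-1.0548	-2.4781	-1.7552	-1.1226	-2.8622	-0.9644	-2.7041	-2.2748	-1.0548	-1.4841	-1.0548	-0.8289	-1.6648	-1.6874	-2.7944	-1.6422	-1.5519
T	-2.2844	-2.4452	-1.0674	-1.0674	-2.5141	-1.7793	-1.1363	-2.9044	-0.9756	-2.7437	-2.3074	-1.0674	-1.5037	-1.0674	-0.8378	-1.6874	-1.7104	-2.8356	-1.6644	-1.5726
V	-3.8633	-4.1511	-1.6844	-1.6844	-4.2744	-2.9589	-1.8078	-4.9733	-1.52	-4.6856	-3.9044	-1.6844	-2.4656	-1.6844	-1.2733	-2.7944	-2.8356	-4.85	-2.7533	-2.5889
W	-2.22	-2.3756	-1.0422	-1.0422	-2.4422	-1.7311	-1.1089	-2.82	-0.9533	-2.6644	-2.2422	-1.0422	-1.4644	-1.0422	-0.82	-1.6422	-1.6644	-2.7533	-1.62	-1.5311
Y	-2.0911	-2.2363	-0.9919	-0.9919	-2.2985	-1.6348	-1.0541	-2.6511	-0.9089	-2.5059	-2.1119	-0.9919	-1.3859	-0.9919	-0.7844	-1.5519	-1.5726	-2.5889	-1.5311	-1.4481
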