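label	toySBS_A	toySBS_B	toySBS_C
A[C>A]A	0.003696	0.001034	0.006114
A[C>A]C	0.006448	0.003194	0.001515
A[C>A]G	0.001447	0.009392	0.006403
A[C>A]T	0.001667	0.000919	0.001243
C[C>A]A	0.006494	0.009464	0.000823
C[C>A]C	0.005761	0.056809	0.016646
C[C>A]G	0.000158	0.002873	0.002125
C[C>A]T	0.001428	0.000405	0.000222
G[C>A]A	0.004511	0.022179	0.002741
G[C>A]C	0.000183	0.00219	0.005036
G[C>A]G	0.039782	0.016901	0.000591
G[C>A]T	0.027222	0.002175	0.032716
T[C>A]A	0.003064	0.001719	0.014309
T[C>A]C	0.00535	0.010529	0.003156
T[C>A]G	0.000739	0.045766	0.004539
T[C>A]T	0.00335	0.042351	0.039898
A[C>G]A	0.124163	0.019635	0.001112
A[C>G]C	0.049839	0.009496	0.002686
A[C>G]G	0.004918	2e-05	0.004328
A[C>G]T	4.9e-05	2.6e-05	0.006214
C[C>G]A	1.3e-05	0.009714	0.007315
C[C>G]C	0.0019	0.028836	0.00078
C[C>G]G	0.00946	0.003562	0.0144
C[C>G]T	0.001033	0.00101	0.002859
G[C>G]A	0.004871	0.00101	0.005009
G[C>G]C	0.001146	0.000569	2.9e-05
G[C>G]G	0.001103	0.003083	0.014837
G[C>G]T	0.036229	0.010696	0.001804
T[C>G]A	0.002408	0.012329	0.007211
T[C>G]C	0.001895	0.027588	0.078212
T[C>G]G	0.048315	0.000247	0.002753
T[C>G]T	0.017798	0.000439	0.024499
A[C>T]A	0.004297	0.001262	0.008922
A[C>T]C	0.006199	0.004221	0.01109
A[C>T]G	0.005894	0.003886	0.024284
A[C>T]T	0.003338	0.000566	0.002975
C[C>T]A	0.000662	0.009231	0.003376
C[C>T]C	0.005163	0.011998	0.019969
C[C>T]G	0.001115	0.003248	0.003583
C[C>T]T	0.018527	2.9e-05	0.016357
G[C>T]A	0.000907	0.008194	0.003608
G[C>T]C	0.005796	0.009767	0.029565
G[C>T]G	0.005047	0.027147	0.000333
G[C>T]T	0.033357	0.012126	0.006031
T[C>T]A	0.001276	0.010392	0.060637
T[C>T]C	0.012508	0.003323	0.004656
T[C>T]G	0.003958	0.014718	1e-06
T[C>T]T	0.005941	0.012071	0.004019
A[T>A]A	0.025809	0.01199	0.020996
A[T>A]C	3e-05	1.4e-05	0.000594
A[T>A]G	0.002334	0.011607	0.00044
A[T>A]T	0.016844	0.010041	0.018791
C[T>A]A	0.002202	0.004862	0.027747
C[T>A]C	1.1e-05	0.005323	0.005867
C[T>A]G	0.000601	0.001601	0.006048
C[T>A]T	0.01309	0.084649	0.018232
G[T>A]A	0.003493	0.000222	0.002381
G[T>A]C	0.013559	0.001888	0.040817
G[T>A]G	0.020448	0.003955	0.031819
G[T>A]T	0.011531	0.000429	0.009486
T[T>A]A	0.003337	3.2e-05	1e-06
T[T>A]C	0.026227	0.017348	0.000852
T[T>A]G	0.010078	0.00033	0.001555
T[T>A]T	0.000266	0.023514	0.003107
A[T>C]A	0.004229	0.019766	0.00103
A[T>C]C	0.003185	0.004376	0.000929
A[T>C]G	0.02019	0.008652	0.009903
A[T>C]T	0.003297	0.000128	0.000432
C[T>C]A	0.001159	0.000298	0.002297
C[T>C]C	0.05699	0.013447	3.7e-05
C[T>C]G	0.002543	2.8e-05	0.021852
C[T>C]T	0.001438	0.002336	0.001016
G[T>C]A	0.001547	0.000234	0.004758
G[T>C]C	0.027327	0.008694	0.010272
G[T>C]G	0.044822	0.003104	0.019905
G[T>C]T	0.000602	0.002111	0.018071
T[T>C]A	0.000147	0.000169	0.003288
T[T>C]C	0.007923	0.000858	0.003878
T[T>C]G	9.8e-05	0.008213	0.005795
T[T>C]T	0.00422	0.026078	0.000991
A[T>G]A	0.00041	0.000385	0.015921
A[T>G]C	0.008885	0.003552	0.019264
A[T>G]G	0.008805	0.115067	0.013547
A[T>G]T	0.004951	0.00446	0.01447
C[T>G]A	0.002403	0.00084	0.001557
C[T>G]C	0.003933	0.00744	0.007333
C[T>G]G	9e-06	0.008558	0.010012
C[T>G]T	0.015134	0.032263	0.028689
G[T>G]A	0.028193	0.038536	0.0304
G[T>G]C	0.015205	0.001303	0.006637
G[T>G]G	0.003202	0.000918	0.000882
G[T>G]T	0.003082	0.000772	0.005221
T[T>G]A	0.035423	0.016969	0.001636
T[T>G]C	0.000805	0.004135	0.020279
T[T>G]G	0.000272	3.2e-05	0.00055
T[T>G]T	0.009288	0.000132	0.018888
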