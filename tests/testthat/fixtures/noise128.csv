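"FP1","FP2","AF3","AF4"
-1.793817,-0.149235,0.968314,1.240546
0.199896,1.178379,-0.957062,-0.446475
0.562451,-0.123305,1.096914,-0.353689
-0.418755,0.732446,-0.991837,1.00713
-0.647794,-0.274517,-2.132138,0.67534
-0.570677,-0.434579,-0.61853,-0.111261
-1.465143,-2.165622,0.306799,0.477753
-0.264948,2.131221,-1.214039,-0.629565
1.157652,-0.978404,-0.664451,0.176915
0.313012,-0.495742,-0.80144,0.175656
0.001057,0.658651,0.183751,1.795073
0.326033,1.028429,-1.44165,-0.786209
-0.143025,1.023078,-0.449865,0.75035
0.079966,-1.426484,-1.33018,1.032393
0.330122,-1.21226,0.140705,-1.185198
0.899362,-0.655146,-1.322792,-1.369616
1.237317,0.345544,-0.935447,0.497401
0.694721,0.710843,-0.877518,-1.876613
0.672611,0.126283,-0.435685,0.205579
0.486449,-0.297686,-0.013884,1.267587
-0.654875,1.583238,0.23112,0.903325
1.25903,-1.751232,0.546809,0.038284
-0.394648,-0.190688,-0.085097,0.219183
-1.005092,-0.196241,-0.570734,-1.268143
-0.637656,-1.260344,-0.297258,-0.262922
-0.394902,0.594854,0.321881,-0.071252
-0.873778,1.794125,-0.395263,0.428806
-1.675773,1.62688,0.55051,-0.072549
1.925291,0.31811,-0.701081,0.439906
0.995666,-0.833558,0.98459,1.001017
1.153262,0.135186,-1.094328,-0.138822
0.239479,0.250638,-0.269653,-0.176208
2.430307,1.261281,0.942195,-0.940144
0.434966,1.368515,-0.01312,1.305434
-0.905802,0.234801,0.789719,-1.180944
-1.157332,0.272269,1.572118,-0.158738
0.477023,-0.471235,-0.649943,-0.038875
0.566814,-1.259282,0.740571,0.47539
0.52273,-0.878105,-0.794221,0.742862
1.075637,0.60752,-1.922003,1.135505
1.968384,0.135432,-1.654996,-0.649885
0.507553,-0.61465,-1.20852,-1.208368
0.994279,0.569677,-0.880798,0.40045
-0.684853,-0.892655,-0.110087,-0.672968
-0.662273,0.129172,0.268019,0.064349
-0.579337,0.881216,0.973681,1.080057
-1.096485,1.266808,-0.50676,-1.497165
-0.297704,-0.112432,0.285953,0.096112
0.148974,0.403312,0.108812,-1.686515
-1.127952,-0.256284,-1.425617,0.315019
1.173542,-1.233465,0.768973,-1.413469
0.513457,0.505433,0.73252,1.047948
-0.477423,-1.518419,0.463226,-0.856069
-0.806479,0.575552,-0.356131,-0.641147
0.106916,-0.054468,-2.366389,0.211445
-0.087873,1.714235,-0.955253,-0.062397
-0.317371,0.849598,0.21431,0.475677
0.548064,-0.629622,-0.154921,-0.477961
-0.373391,-0.421227,0.275833,1.89449
0.015092,1.871295,0.07061,0.595562
0.626537,0.568999,-0.009008,-0.467802
1.291785,1.188073,-0.296483,-0.346588
1.476073,-0.834553,-1.046007,-0.64672
0.198299,-1.826249,-0.019185,-1.32495
-0.970055,-0.196549,-0.040879,-0.305391
-0.725903,-0.399932,2.297307,1.97912
0.866405,1.090702,0.361857,1.92165
0.260408,1.539252,0.948529,0.986044
-1.258492,0.0223,-1.732932,-0.553524
-0.678106,-0.575126,-0.365755,-0.948918
0.072037,-0.380093,1.605485,-0.720437
-1.682596,1.672848,-0.524564,1.838239
0.756419,0.092695,-0.234284,0.345974
-0.346508,0.181722,-0.523084,0.433263
-2.119936,-0.629868,0.490206,-1.237099
0.584531,0.941398,-0.196888,1.442872
1.200979,0.632099,0.430826,-1.714889
2.031986,-0.438975,0.081934,-1.115382
1.343673,0.501308,1.036771,-0.390519
-0.012146,-1.436562,-0.426015,0.785794
-2.229959,-0.084172,0.99045,-1.629297
0.320174,0.452239,-2.15503,0.164599
-1.77017,1.27374,0.567946,1.622198
-1.324221,0.284298,-0.350737,-1.181715
0.57079,0.06657,0.950132,-0.676351
0.761949,0.708047,0.173465,0.467919
-0.280927,0.271141,1.698675,0.576858
-0.437303,0.923708,-1.057621,-0.595716
-1.577227,0.565631,0.151718,0.73619
0.984731,0.303254,0.404668,1.463661
-1.766312,-1.586012,-0.460712,0.913216
1.093256,0.176361,-0.165312,-0.086547
-1.063432,2.107161,-1.282578,0.295108
-0.542756,-1.327601,1.167125,-0.318573
-0.470861,1.067299,-0.858117,0.56853
-0.236591,-1.188496,-0.983748,-0.784571
1.014998,-0.042981,0.428773,0.758439
1.781693,-0.050086,-0.377561,0.927799
-0.307586,0.675764,-0.229149,0.446213
1.355129,0.477061,0.147723,0.430594
0.238723,0.645559,1.779277,-0.219779
0.537554,-0.257992,0.528296,-0.777277
-0.020286,1.556194,0.430732,-0.513562
1.057969,-0.175952,-0.887144,-0.696004
-0.34718,1.618017,-1.366191,0.809437
-0.123947,0.322956,0.582549,1.126911
-2.516955,1.360189,2.479076,-0.5343
0.244385,-0.730924,1.784372,-1.17789
-0.402594,1.152938,2.110787,0.49826
0.258689,0.987928,-0.351372,0.187256
-1.855159,0.961357,0.197809,-1.099805
-1.206725,-1.848611,0.159461,-1.75207
1.826229,0.71741,0.346294,-0.234004
0.061545,0.315964,1.32044,-0.078555
0.534715,-1.266712,1.141738,-0.258207
-0.961318,0.544022,0.794253,0.75314
-0.488912,-0.054367,-0.141933,1.181922
0.792136,0.405738,1.569972,-0.243577
2.343914,0.043774,-0.065396,-0.208609
-1.557568,0.497936,-2.311005,-1.107787
-1.550807,0.558302,0.059214,-1.545658
1.12221,-0.985112,-0.846066,0.936408
-0.193535,0.515468,0.068636,-0.27101
0.537776,1.819475,-1.456703,-1.227108
0.494409,0.022248,1.572595,0.683173
-2.001035,0.959594,0.15433,2.188411
-0.775206,0.651283,0.349958,-0.600357
0.064542,0.321836,2.625328,0.498206
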