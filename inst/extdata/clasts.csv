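id,axis1_mm,axis2_mm,axis3_mm,mass_g,lithology
G001,8.76343933643309,4.77314523802944,1.5432675710428,0.1,chert
G002,19.8171963901968,16.976755385574,4.36533585640398,2,quartzite
G003,14.4648912535814,11.1836213748229,3.73953157865827,0.8,quartzite
G004,58.1897375408733,44.6993103592951,15.9478076401711,57.6,quartzite
G005,32.2625323151855,25.5924990672387,12.7121782388457,14.6,chert
G006,20.6239088126488,19.4235472060337,11.6136781746334,6.5,chert
G007,12.2190144494748,9.73712558602268,3.5289541073522,0.6,chert
G008,25.676053383662,22.6168309209196,9.74424211421299,7.9,chert
G009,8.73026476273288,6.89848285738056,2.64228963184955,0.2,quartzite
G010,13.0020990002759,9.88615672806226,8.77120622805683,1.6,chert
G011,12.6801185445577,10.9194850238867,3.19050260989912,0.6,chert
G012,13.9075326568233,8.78890602122618,3.33639458399246,0.6,chert
G013,11.1809560781212,9.75177881475905,5.59485566974737,0.8,chert
G014,16.7132626898035,9.44983939594408,7.31840687241385,1.6,quartzite
G015,24.6202519843354,20.9903933266872,5.16455432669477,3.7,quartzite
G016,28.4446137547298,11.5549921829299,8.63875403832737,3.9,chert
G017,11.2060919643039,6.59326254436474,2.0727313021932,0.2,chert
G018,17.5428922928016,15.8282160000636,6.6226931901499,2.6,chert
G019,42.4946182969178,36.0204834437484,27.4580650669556,58.3,quartzite
G020,22.0313612616051,9.72151250503447,5.29548932871495,1.6,chert
G021,19.4495735734512,16.9174400880083,8.76796579019893,4,quartzite
G022,22.3202481666692,17.5346618676016,8.54271007891665,4.6,quartzite
G023,21.1140934270444,19.3563767458092,13.9959692360872,7.9,chert
G024,18.5531681929847,15.3617562887212,7.3028615544042,2.9,quartzite
G025,14.8305639389766,7.57285446466493,3.08507649561746,0.5,quartzite
G026,22.2588014468545,11.8031075400046,8.53673158971765,3.1,quartzite
G027,23.8670490713828,18.9424031766604,11.3986822748425,7.2,chert
G028,25.4326342543704,20.5865191524048,4.95451659223781,3.6,chert
G029,10.2633127387555,9.4157066304715,5.44327456431327,0.7,chert
G030,24.5922952364174,13.0056155060104,10.4205096436607,4.6,quartzite
G031,9.60616952852479,8.37130054496589,6.92256006377922,0.8,quartzite
G032,24.5337320244441,18.0479309192691,8.64477470116643,5.3,chert
G033,23.2000683800666,19.5486669445967,11.955912883897,7.5,quartzite
G034,15.3135088338965,12.8213151143092,4.83051617376094,1.3,quartzite
G035,33.673134798633,29.2676477947647,14.696778391674,20.1,chert
G036,8.08379486608033,7.51648922974523,2.65858700247622,0.2,quartzite
G037,14.2048009503598,6.6642091559715,5.99065942397151,0.8,chert
G038,9.61122716828075,5.00163547888571,3.77437837228388,0.3,chert
G039,10.7204084596179,4.49029030506629,1.11720298296241,0.1,chert
G040,12.0444221850735,9.19823718830779,4.65030055940055,0.7,quartzite
G041,10.2495127356674,5.73643969946164,4.2884016347816,0.3,chert
G042,10.2760097024001,8.15947573481592,3.6611832839308,0.4,quartzite
G043,27.9826626217217,10.6896698666452,8.14698392343817,3.4,chert
G044,9.847896246582,9.15644756003379,3.51691392777818,0.4,chert
G045,7.89499555030089,7.08533045017458,1.89260956757612,0.1,quartzite
G046,26.7530905568599,24.8556968435248,9.17889317175639,8.5,quartzite
G047,21.4199466071474,9.31346132729359,3.30237581389413,0.9,chert
G048,17.0917348667674,15.5229297577597,12.9371224531605,4.8,quartzite
G049,16.2999630577875,12.0625734904437,5.59926525794966,1.5,quartzite
G050,21.5671211315585,18.1000998434973,6.08350864894415,3.3,chert
G051,10.3000379475531,8.89159042273836,3.64376911568001,0.5,chert
G052,37.9455696411799,29.9723120831199,9.59280797072328,15.1,quartzite
G053,17.7402069288801,16.3559351975377,7.29488466971501,2.9,quartzite
G054,28.7561932909708,21.8680887181473,10.0839865298021,8.8,quartzite
G055,6.08168523529014,5.74574948906144,3.20361403717092,0.2,chert
G056,24.622132863773,9.82262525950751,2.58157333855397,0.9,chert
G057,19.0765959262443,15.9955109790895,5.24947987425137,2.2,chert
G058,18.4829049422267,16.2508616318562,15.7412431529841,6.6,quartzite
G059,24.6940685493088,22.0262193985883,5.54753416539004,4.2,chert
G060,16.6779692862343,11.6305185882436,5.22273139610897,1.4,chert
G061,7.75376062782846,6.37811166995652,3.14368711340363,0.2,quartzite
G062,3.72200896379952,2.99854008882316,1.64716881123638,0.1,chert
G063,20.0018353741658,8.79410034836612,5.4607681907088,1.3,quartzite
G064,11.8339417157882,8.51069481632277,2.34286990974379,0.3,chert
G065,24.8406528737444,14.0145821459625,5.96485669808723,2.9,quartzite
G066,19.7118955130416,16.0700510619564,6.93073676780403,3,chert
G067,25.6209467459566,21.6149143496709,7.92359011240576,6.1,chert
G068,12.6882687098136,10.7919354299985,4.0440606553762,0.8,chert
G069,13.6274807331367,10.5700736281222,7.71733100542183,1.5,chert
G070,13.0395218884902,9.89477149112669,8.93518062704328,1.6,chert
G071,20.0962501775587,19.0105037672241,8.30531614956171,4.4,chert
G072,24.6230699402049,21.2693051671601,8.70502353653601,6.3,quartzite
G073,16.5830739378613,16.1285768377659,8.44711499656025,3.1,chert
G074,16.4564777086033,8.23846058914238,6.64304353003012,1.2,quartzite
G075,29.6376686489438,14.3173794602899,4.48304220520789,2.6,quartzite
G076,17.7848370250871,16.3578081929155,6.64113988198111,2.7,quartzite
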