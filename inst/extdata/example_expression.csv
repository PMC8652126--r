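gene,c1,c2,c3,c4,c5,c6,c7,c8,c9,c10
g1,-0.05859836916763819,-1.071847051450216,2.295085279389321,0.9103562830183561,-0.18459723531473404,2.9403414896884263,-0.7793606452949049,-0.7951363681329193,1.219862757058214,0.41474496013607876
g2,-2.391521463419873,-4.030439023472814,0.16483682464724358,0.5995954287390728,2.2645040479161174,2.723358537837746,-0.833773161737308,-0.882457682919507,-0.3870770457446093,0.05606084217025587
g3,-0.4859675233897076,1.8037597538502814,0.20263647287556424,-1.3943823858640523,-1.1589618719151598,-0.914062690798219,0.29379106069095334,-1.0056317857947084,-1.3003886001486251,0.19354764640222877
g4,1.7094134885858865,1.1300274329060063,-0.8067388268263745,-0.3970308167164514,-1.2187537552189156,-0.8683818942785746,0.834351091400515,1.5047156049416843,0.39110401027402975,1.6699445720897765
g5,-0.9040980729180403,-0.35311825779715167,-0.15904222795827835,-0.68809534731814,1.088909629528106,-0.8083863587334386,-0.17451719434087992,-0.1290375002578155,-1.0442788608637903,0.13369525216389602
g6,-0.27743279810578736,1.1069374930087024,0.7342484049279058,-0.7765219478670646,1.5121332877234746,0.5287368248712255,0.24009954716450072,0.026981548107921,0.5988934255259019,-1.2601680552436327
g7,1.6306616767959663,2.663224696456239,-0.4490622267988635,1.4322832865038262,-0.29245805431665517,-1.0287714419439473,-0.8072686894239871,0.3988101023975014,1.1272464956747528,0.11915629930100502
g8,-0.06040411713390845,2.064308730467173,-0.010094030409008335,0.45655551273747325,0.3145689451948603,-0.24340044967878238,-2.087355428376872,0.5445282513941978,0.5986795544191252,0.7444603672829264
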