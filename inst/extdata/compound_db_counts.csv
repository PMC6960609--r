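class,emotion,CASME1,CASME2,CASME_SQ2,SAMM
Pos,happiness,9,32,15,26
Neg,disgust,44,64,16,9
Neg,fear,2,2,4,8
Neg,anger,0,0,7,57
Neg,sadness,6,7,1,6
Sur,surprise,20,25,10,15
PS,happily surprised,16,18,20,20
NS,sadly surprised,5,19,0,7
NS,fearfully surprised,0,0,8,8
NS,angrily surprised,0,0,12,26
NS,disgustedly surprised,62,73,16,0
PN,happily disgusted,6,143,13,35
NN,sadly fearful,2,0,0,7
NN,sadly angry,0,0,0,18
NN,sadly disgusted,28,52,0,1
NN,fearfully angry,0,0,2,2
NN,fearfully disgusted,0,0,5,0
NN,angrily disgusted,0,0,10,31
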