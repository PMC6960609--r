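table,emotion,au,role,proportion
micro,happiness,6,prototypical,1
micro,happiness,12,prototypical,1
micro,sadness,1,prototypical,1
micro,sadness,4,prototypical,1
micro,sadness,15,prototypical,1
micro,fear,1,prototypical,1
micro,fear,4,prototypical,1
micro,fear,20,prototypical,1
micro,anger,4,prototypical,1
micro,anger,7,prototypical,1
micro,anger,43,prototypical,1
micro,disgust,4,prototypical,1
micro,disgust,7,prototypical,1
micro,disgust,9,prototypical,1
micro,disgust,25,prototypical,1
micro,disgust,26,prototypical,1
micro,surprise,1,prototypical,1
micro,surprise,2,prototypical,1
micro,surprise,5,prototypical,1
macro,happiness,12,prototypical,1
macro,happiness,25,prototypical,1
macro,happiness,6,prototypical,1
macro,sadness,4,prototypical,1
macro,sadness,15,prototypical,1
macro,sadness,1,secondary,0.60
macro,sadness,6,secondary,0.50
macro,sadness,11,secondary,0.26
macro,sadness,17,secondary,0.67
macro,fear,1,prototypical,1
macro,fear,4,prototypical,1
macro,fear,20,prototypical,1
macro,fear,25,prototypical,1
macro,fear,2,secondary,0.57
macro,fear,5,secondary,0.63
macro,fear,26,secondary,0.33
macro,anger,4,prototypical,1
macro,anger,7,prototypical,1
macro,anger,24,prototypical,1
macro,anger,10,secondary,0.26
macro,anger,17,secondary,0.52
macro,anger,23,secondary,0.29
macro,surprise,1,prototypical,1
macro,surprise,2,prototypical,1
macro,surprise,25,prototypical,1
macro,surprise,26,prototypical,1
macro,surprise,5,secondary,0.66
macro,disgust,9,prototypical,1
macro,disgust,10,prototypical,1
macro,disgust,17,prototypical,1
macro,disgust,4,secondary,0.31
macro,disgust,24,secondary,0.26
macro,happily surprised,1,prototypical,1
macro,happily surprised,2,prototypical,1
macro,happily surprised,12,prototypical,1
macro,happily surprised,25,prototypical,1
macro,happily surprised,5,secondary,0.64
macro,happily surprised,26,secondary,0.67
macro,happily disgusted,10,prototypical,1
macro,happily disgusted,12,prototypical,1
macro,happily disgusted,25,prototypical,1
macro,happily disgusted,4,secondary,0.32
macro,happily disgusted,6,secondary,0.61
macro,happily disgusted,9,secondary,0.59
macro,sadly fearful,1,prototypical,1
macro,sadly fearful,4,prototypical,1
macro,sadly fearful,20,prototypical,1
macro,sadly fearful,25,prototypical,1
macro,sadly fearful,2,secondary,0.46
macro,sadly fearful,5,secondary,0.24
macro,sadly fearful,6,secondary,0.34
macro,sadly fearful,15,secondary,0.30
macro,sadly angry,4,prototypical,1
macro,sadly angry,15,prototypical,1
macro,sadly angry,6,secondary,0.26
macro,sadly angry,7,secondary,0.48
macro,sadly angry,11,secondary,0.20
macro,sadly angry,17,secondary,0.50
macro,sadly surprised,1,prototypical,1
macro,sadly surprised,4,prototypical,1
macro,sadly surprised,25,prototypical,1
macro,sadly surprised,26,prototypical,1
macro,sadly surprised,2,secondary,0.27
macro,sadly surprised,6,secondary,0.31
macro,sadly disgusted,4,prototypical,1
macro,sadly disgusted,10,prototypical,1
macro,sadly disgusted,25,prototypical,1
macro,sadly disgusted,1,secondary,0.49
macro,sadly disgusted,6,secondary,0.61
macro,sadly disgusted,9,secondary,0.20
macro,sadly disgusted,11,secondary,0.35
macro,sadly disgusted,15,secondary,0.54
macro,sadly disgusted,17,secondary,0.47
macro,fearfully angry,4,prototypical,1
macro,fearfully angry,20,prototypical,1
macro,fearfully angry,25,prototypical,1
macro,fearfully angry,5,secondary,0.40
macro,fearfully angry,7,secondary,0.39
macro,fearfully angry,10,secondary,0.30
macro,fearfully surprised,1,prototypical,1
macro,fearfully surprised,2,prototypical,1
macro,fearfully surprised,5,prototypical,1
macro,fearfully surprised,20,prototypical,1
macro,fearfully surprised,25,prototypical,1
macro,fearfully surprised,4,secondary,0.47
macro,fearfully surprised,26,secondary,0.51
macro,fearfully disgusted,1,prototypical,1
macro,fearfully disgusted,4,prototypical,1
macro,fearfully disgusted,10,prototypical,1
macro,fearfully disgusted,20,prototypical,1
macro,fearfully disgusted,25,prototypical,1
macro,fearfully disgusted,2,secondary,0.64
macro,fearfully disgusted,5,secondary,0.50
macro,fearfully disgusted,9,secondary,0.28
macro,fearfully disgusted,15,secondary,0.33
macro,angrily surprised,4,prototypical,1
macro,angrily surprised,25,prototypical,1
macro,angrily surprised,26,prototypical,1
macro,angrily surprised,5,secondary,0.35
macro,angrily surprised,7,secondary,0.50
macro,angrily surprised,10,secondary,0.34
macro,angrily disgusted,4,prototypical,1
macro,angrily disgusted,10,prototypical,1
macro,angrily disgusted,17,prototypical,1
macro,angrily disgusted,7,secondary,0.60
macro,angrily disgusted,9,secondary,0.57
macro,angrily disgusted,24,secondary,0.36
macro,disgustedly surprised,1,prototypical,1
macro,disgustedly surprised,2,prototypical,1
macro,disgustedly surprised,5,prototypical,1
macro,disgustedly surprised,10,prototypical,1
macro,disgustedly surprised,4,secondary,0.45
macro,disgustedly surprised,9,secondary,0.37
macro,disgustedly surprised,17,secondary,0.66
macro,disgustedly surprised,24,secondary,0.33
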