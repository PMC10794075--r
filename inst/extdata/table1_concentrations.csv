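variety,sample,Glc,Fru,Suc,GF2,GF3,GF4
Valencia orange,A,18.5,21.6,41.3,5.0,6.4,1.0
Valencia orange,B,19.0,21.8,41.7,6.6,8.5,0.7
Valencia orange,C,19.2,22.0,41.8,8.2,10.9,1.5
Valencia orange,D,19.6,22.3,42.5,12.4,16.5,2.2
Valencia orange,E,25.8,22.7,44.2,8.1,8.0,1.0
Valencia orange,F,27.7,23.1,45.2,10.0,10.2,1.4
Valencia orange,G,30.8,33.6,22.0,4.9,6.4,1.0
Valencia orange,H,31.6,34.4,22.6,6.6,8.7,0.9
Valencia orange,I,39.3,36.0,25.9,8.2,8.2,1.1
Valencia orange,J,40.4,35.8,26.2,10.0,10.3,1.4
Mandarin orange,K,20.4,22.3,50.8,5.8,7.6,1.0
Mandarin orange,L,20.2,22.2,50.6,7.5,10.0,1.4
Citrus unshiu,M,13.1,15.6,44.0,6.8,8.9,1.2
Citrus unshiu,N,20.1,16.5,47.0,8.3,8.4,1.1
White grapefruit,O,20.8,21.6,22.2,5.6,7.5,1.0
White grapefruit,P,28.1,23.6,26.0,7.0,7.1,0.9
Ruby grapefruit,Q,20.8,21.5,22.9,7.3,9.8,1.3
Ruby grapefruit,R,29.3,23.2,26.8,9.1,9.2,1.3
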