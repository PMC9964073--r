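trial,X1,X2,X3,quantity,Y1,Y2
1,1.6,0.15,1.0,predicted,77.3,46.6
1,1.6,0.15,1.0,experimental,83.2,49.1
1,1.6,0.15,1.0,error,7.63,5.3
1,1.6,0.15,1.0,desirability,0.92,
2,1.5,0.2,1.5,predicted,88.6,47.2
2,1.5,0.2,1.5,experimental,87.0,42.3
2,1.5,0.2,1.5,error,1.8,10.3
2,1.5,0.2,1.5,desirability,0.99,
3,1.5,0.2,0.5,predicted,83.1,49.1
3,1.5,0.2,0.5,experimental,90.0,47.2
3,1.5,0.2,0.5,error,8.3,3.8
3,1.5,0.2,0.5,desirability,0.90,
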