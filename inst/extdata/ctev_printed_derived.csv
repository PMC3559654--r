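participant,quantity,side,printed
C1,V_Leg_ratio,NA,1.0
C2,V_Leg_ratio,NA,0.97
C3,V_Leg_ratio,NA,1.05
C4,V_Leg_ratio,NA,0.99
C5,V_Leg_ratio,NA,1.0
B1,V_Leg_ratio,NA,1.02
B2,V_Leg_ratio,NA,0.99
U1,V_Leg_ratio,NA,0.92
U2,V_Leg_ratio,NA,0.85
U3,V_Leg_ratio,NA,0.72
U4,V_Leg_ratio,NA,0.83
C1,V_Musc_ratio,NA,1.02
C2,V_Musc_ratio,NA,0.99
C3,V_Musc_ratio,NA,1.07
C4,V_Musc_ratio,NA,1.02
C5,V_Musc_ratio,NA,0.98
B1,V_Musc_ratio,NA,1.45
B2,V_Musc_ratio,NA,0.97
U1,V_Musc_ratio,NA,0.65
U2,V_Musc_ratio,NA,0.63
U3,V_Musc_ratio,NA,0.48
U4,V_Musc_ratio,NA,0.62
C1,V_Fat_ratio,NA,1.04
C2,V_Fat_ratio,NA,0.93
C3,V_Fat_ratio,NA,0.98
C4,V_Fat_ratio,NA,0.98
C5,V_Fat_ratio,NA,1.08
B1,V_Fat_ratio,NA,0.97
B2,V_Fat_ratio,NA,0.99
U1,V_Fat_ratio,NA,1.15
U2,V_Fat_ratio,NA,1.04
U3,V_Fat_ratio,NA,1.0
U4,V_Fat_ratio,NA,1.01
C1,V_Tibia_ratio,NA,0.99
C2,V_Tibia_ratio,NA,1.0
C3,V_Tibia_ratio,NA,1.05
C4,V_Tibia_ratio,NA,1.01
C5,V_Tibia_ratio,NA,1.02
B1,V_Tibia_ratio,NA,0.9
B2,V_Tibia_ratio,NA,0.99
U1,V_Tibia_ratio,NA,0.88
U2,V_Tibia_ratio,NA,0.96
U3,V_Tibia_ratio,NA,0.85
U4,V_Tibia_ratio,NA,0.98
C1,V_Fibula_ratio,NA,0.99
C2,V_Fibula_ratio,NA,1.05
C3,V_Fibula_ratio,NA,1.01
C4,V_Fibula_ratio,NA,1.0
C5,V_Fibula_ratio,NA,1.07
B1,V_Fibula_ratio,NA,1.11
B2,V_Fibula_ratio,NA,0.97
U1,V_Fibula_ratio,NA,0.96
U2,V_Fibula_ratio,NA,0.87
U3,V_Fibula_ratio,NA,0.8
U4,V_Fibula_ratio,NA,0.91
C1,TA_Musc_ratio,NA,0.57
C2,TA_Musc_ratio,NA,0.93
C3,TA_Musc_ratio,NA,1.23
C4,TA_Musc_ratio,NA,0.91
C5,TA_Musc_ratio,NA,1.05
B1,TA_Musc_ratio,NA,0.83
B2,TA_Musc_ratio,NA,0.77
U1,TA_Musc_ratio,NA,2.72
U2,TA_Musc_ratio,NA,3.08
U3,TA_Musc_ratio,NA,5.73
U4,TA_Musc_ratio,NA,4.12
C1,Muscle_pct,right,62.3
C1,Muscle_pct,left,62.6
C2,Muscle_pct,right,56.4
C2,Muscle_pct,left,55.0
C3,Muscle_pct,right,68.8
C3,Muscle_pct,left,66.9
C4,Muscle_pct,right,51
C4,Muscle_pct,left,49.9
C5,Muscle_pct,right,62.4
C5,Muscle_pct,left,64.6
B1,Muscle_pct,right,20.3
B1,Muscle_pct,left,14.5
B2,Muscle_pct,right,51.3
B2,Muscle_pct,left,51.7
U1,Muscle_pct,affected,36.9
U1,Muscle_pct,unaffected,50.9
U2,Muscle_pct,affected,43.3
U2,Muscle_pct,unaffected,55.7
U3,Muscle_pct,affected,45.7
U3,Muscle_pct,unaffected,63.7
U4,Muscle_pct,affected,52.9
U4,Muscle_pct,unaffected,64.8
C1,Fat_pct,right,37.7
C1,Fat_pct,left,37.4
C2,Fat_pct,right,43.6
C2,Fat_pct,left,45.0
C3,Fat_pct,right,31.2
C3,Fat_pct,left,33.1
C4,Fat_pct,right,49.0
C4,Fat_pct,left,50.1
C5,Fat_pct,right,37.6
C5,Fat_pct,left,35.4
B1,Fat_pct,right,79.7
B1,Fat_pct,left,85.5
B2,Fat_pct,right,48.7
B2,Fat_pct,left,48.3
U1,Fat_pct,affected,63.1
U1,Fat_pct,unaffected,49.1
U2,Fat_pct,affected,56.7
U2,Fat_pct,unaffected,44.3
U3,Fat_pct,affected,54.3
U3,Fat_pct,unaffected,36.3
U4,Fat_pct,affected,47.1
U4,Fat_pct,unaffected,35.2
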