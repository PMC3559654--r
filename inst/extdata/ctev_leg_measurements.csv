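participant,group,side,side_status,measurement,value,units
C1,control,right,right,V_Leg,2511.1,cm3
C1,control,left,left,V_Leg,2499.1,cm3
C1,control,right,right,V_Musc,1262.4,cm3
C1,control,left,left,V_Musc,1233.8,cm3
C1,control,right,right,V_Fat,765.5,cm3
C1,control,left,left,V_Fat,736.3,cm3
C1,control,right,right,V_Tibia,249.0,cm3
C1,control,left,left,V_Tibia,251.8,cm3
C1,control,right,right,V_Fibula,46.2,cm3
C1,control,left,left,V_Fibula,46.6,cm3
C1,control,right,right,TA_Musc,0.63,percent
C1,control,left,left,TA_Musc,1.09,percent
C2,control,right,right,V_Leg,2221.4,cm3
C2,control,left,left,V_Leg,2293.1,cm3
C2,control,right,right,V_Musc,968.3,cm3
C2,control,left,left,V_Musc,982.7,cm3
C2,control,right,right,V_Fat,748.3,cm3
C2,control,left,left,V_Fat,802.5,cm3
C2,control,right,right,V_Tibia,241.1,cm3
C2,control,left,left,V_Tibia,241.9,cm3
C2,control,right,right,V_Fibula,42.4,cm3
C2,control,left,left,V_Fibula,40.4,cm3
C2,control,right,right,TA_Musc,2.2,percent
C2,control,left,left,TA_Musc,2.36,percent
C3,control,right,right,V_Leg,2382.7,cm3
C3,control,left,left,V_Leg,2268.8,cm3
C3,control,right,right,V_Musc,1271.0,cm3
C3,control,left,left,V_Musc,1192.7,cm3
C3,control,right,right,V_Fat,576.0,cm3
C3,control,left,left,V_Fat,589.9,cm3
C3,control,right,right,V_Tibia,284.1,cm3
C3,control,left,left,V_Tibia,271.6,cm3
C3,control,right,right,V_Fibula,41.9,cm3
C3,control,left,left,V_Fibula,41.7,cm3
C3,control,right,right,TA_Musc,0.9,percent
C3,control,left,left,TA_Musc,0.73,percent
C4,control,right,right,V_Leg,2922.9,cm3
C4,control,left,left,V_Leg,2947.3,cm3
C4,control,right,right,V_Musc,1203.8,cm3
C4,control,left,left,V_Musc,1181.2,cm3
C4,control,right,right,V_Fat,1157.2,cm3
C4,control,left,left,V_Fat,1186.9,cm3
C4,control,right,right,V_Tibia,270.4,cm3
C4,control,left,left,V_Tibia,269.0,cm3
C4,control,right,right,V_Fibula,51.1,cm3
C4,control,left,left,V_Fibula,51.2,cm3
C4,control,right,right,TA_Musc,1.54,percent
C4,control,left,left,TA_Musc,1.68,percent
C5,control,right,right,V_Leg,1993.2,cm3
C5,control,left,left,V_Leg,2000.2,cm3
C5,control,right,right,V_Musc,1010.4,cm3
C5,control,left,left,V_Musc,1029.4,cm3
C5,control,right,right,V_Fat,607.8,cm3
C5,control,left,left,V_Fat,564.5,cm3
C5,control,right,right,V_Tibia,203.3,cm3
C5,control,left,left,V_Tibia,198.4,cm3
C5,control,right,right,V_Fibula,34.7,cm3
C5,control,left,left,V_Fibula,32.4,cm3
C5,control,right,right,TA_Musc,2.12,percent
C5,control,left,left,TA_Musc,2.03,percent
B1,bilateral,right,right,V_Leg,2278.3,cm3
B1,bilateral,left,left,V_Leg,2244.4,cm3
B1,bilateral,right,right,V_Musc,343.0,cm3
B1,bilateral,left,left,V_Musc,236.6,cm3
B1,bilateral,right,right,V_Fat,1344.7,cm3
B1,bilateral,left,left,V_Fat,1389.8,cm3
B1,bilateral,right,right,V_Tibia,288.6,cm3
B1,bilateral,left,left,V_Tibia,320.9,cm3
B1,bilateral,right,right,V_Fibula,57.9,cm3
B1,bilateral,left,left,V_Fibula,52.0,cm3
B1,bilateral,right,right,TA_Musc,16.38,percent
B1,bilateral,left,left,TA_Musc,19.71,percent
B2,bilateral,right,right,V_Leg,2595.4,cm3
B2,bilateral,left,left,V_Leg,2622.0,cm3
B2,bilateral,right,right,V_Musc,1052.6,cm3
B2,bilateral,left,left,V_Musc,1080.8,cm3
B2,bilateral,right,right,V_Fat,1000.5,cm3
B2,bilateral,left,left,V_Fat,1008.9,cm3
B2,bilateral,right,right,V_Tibia,287.1,cm3
B2,bilateral,left,left,V_Tibia,289.4,cm3
B2,bilateral,right,right,V_Fibula,41.3,cm3
B2,bilateral,left,left,V_Fibula,42.6,cm3
B2,bilateral,right,right,TA_Musc,2.43,percent
B2,bilateral,left,left,TA_Musc,3.15,percent
U1,unilateral,right,affected,V_Leg,3011.8,cm3
U1,unilateral,left,unaffected,V_Leg,3275.2,cm3
U1,unilateral,right,affected,V_Musc,882.9,cm3
U1,unilateral,left,unaffected,V_Musc,1358.8,cm3
U1,unilateral,right,affected,V_Fat,1511.3,cm3
U1,unilateral,left,unaffected,V_Fat,1309.6,cm3
U1,unilateral,right,affected,V_Tibia,216.4,cm3
U1,unilateral,left,unaffected,V_Tibia,247.0,cm3
U1,unilateral,right,affected,V_Fibula,28.18,cm3
U1,unilateral,left,unaffected,V_Fibula,29.2,cm3
U1,unilateral,right,affected,TA_Musc,4.8,percent
U1,unilateral,left,unaffected,TA_Musc,1.77,percent
U2,unilateral,left,affected,V_Leg,2724.4,cm3
U2,unilateral,right,unaffected,V_Leg,3219.5,cm3
U2,unilateral,left,affected,V_Musc,940.8,cm3
U2,unilateral,right,unaffected,V_Musc,1488.2,cm3
U2,unilateral,left,affected,V_Fat,1232.0,cm3
U2,unilateral,right,unaffected,V_Fat,1183.6,cm3
U2,unilateral,left,affected,V_Tibia,261.1,cm3
U2,unilateral,right,unaffected,V_Tibia,273.1,cm3
U2,unilateral,left,affected,V_Fibula,41.1,cm3
U2,unilateral,right,unaffected,V_Fibula,47.2,cm3
U2,unilateral,left,affected,TA_Musc,3.38,percent
U2,unilateral,right,unaffected,TA_Musc,1.1,percent
U3,unilateral,left,affected,V_Leg,1240.5,cm3
U3,unilateral,right,unaffected,V_Leg,1717.0,cm3
U3,unilateral,left,affected,V_Musc,410.7,cm3
U3,unilateral,right,unaffected,V_Musc,854.7,cm3
U3,unilateral,left,affected,V_Fat,488.7,cm3
U3,unilateral,right,unaffected,V_Fat,486.5,cm3
U3,unilateral,left,affected,V_Tibia,159.4,cm3
U3,unilateral,right,unaffected,V_Tibia,187.0,cm3
U3,unilateral,left,affected,V_Fibula,16.4,cm3
U3,unilateral,right,unaffected,V_Fibula,20.6,cm3
U3,unilateral,left,affected,TA_Musc,6.21,percent
U3,unilateral,right,unaffected,TA_Musc,1.08,percent
U4,unilateral,left,affected,V_Leg,1291.7,cm3
U4,unilateral,right,unaffected,V_Leg,1551.7,cm3
U4,unilateral,left,affected,V_Musc,440.4,cm3
U4,unilateral,right,unaffected,V_Musc,712.5,cm3
U4,unilateral,left,affected,V_Fat,392.7,cm3
U4,unilateral,right,unaffected,V_Fat,387.0,cm3
U4,unilateral,left,affected,V_Tibia,250.5,cm3
U4,unilateral,right,unaffected,V_Tibia,256.7,cm3
U4,unilateral,left,affected,V_Fibula,33.4,cm3
U4,unilateral,right,unaffected,V_Fibula,36.7,cm3
U4,unilateral,left,affected,TA_Musc,7.88,percent
U4,unilateral,right,unaffected,TA_Musc,1.91,percent
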