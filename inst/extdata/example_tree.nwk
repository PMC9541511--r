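(t006:60,(t005:53.6888454111,((((t004:25.9120444087,t008:25.9120444087)N20:7.41265785401,((t002:2.31565230122,t003:2.31565230122)N22:26.5451265293,t001:28.8607788305)N19:4.46392343215)N18:7.00401082994,t009:40.3287130926)N16:3.02614741492,((t012:1.46365177323,t007:1.46365177323)N23:36.9630976234,(t010:21.4802743687,t011:21.4802743687)N21:16.9464750279)N17:4.92811111093)N15:10.3339849035)N14:6.31115458891)N13;
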