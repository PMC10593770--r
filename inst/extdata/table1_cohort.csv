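patient,genetic_diagnosis,heteroplasmy,sex,age_at_death
Patient 1,m.3243A>G,Muscle: 85%,M,45
Patient 2,m.3243A>G,Muscle: 77%,F,64
Patient 3,m.3243A>G,Muscle: 83%,M,54
Patient 4,m.3243A>G,Muscle: 53%,M,61
Patient 5,m.3243A>G,Muscle: 71%,M,30
Patient 6,m.8344A>G,Blood: 92%,F,42
Patient 7,m.8344A>G,Urine: 70%,M,58
Patient 8,m.8344A>G,Muscle: 98%,M,31
Patient 9,POLG (p.Gly848Ser and p.Ser1104Cys),,M,59
Patient 10,POLG (p.Thr251Ile/p.Pro587Leu and p.Ala467Thr),,M,79
Patient 11,POLG (p.Trp748Ser; p.Arg1096Cys and p.Glu1143Gly),,M,55
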