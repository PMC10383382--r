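id,cas,name,smiles,ec50_mM,predicted_ec50_pls,observed_class_printed,predicted_class_lda,split,glide_energy_kcal_mol,smiles_provenance
C1,375-22-4,Perfluorobutanoic acid (PFBA),OC(=O)C(F)(F)C(F)(F)C(F)(F)F,2.61,2.87,L,L,train,-19.583,"written from CAS/name, neutral form"
C2,2706-90-3,Perfluoropentanoic acid (PFPeA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,2.14,2.09,L,L,train,-21.171,"written from CAS/name, neutral form"
C3,307-24-4,Perfluorohexanoic acid (PFHxA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.40,1.41,L,L,train,-20.473,"written from CAS/name, neutral form"
C4,375-85-9,Perfluoroheptanoic acid (PFHpA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.68,0.55,H,H,train,-31.114,"written from CAS/name, neutral form"
C5,335-67-1,Perfluorooctanoic acid (PFOA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.84,0.78,H,H,test,-33.059,"written from CAS/name, neutral form"
C6,375-95-1,Perfluorononanoic acid (PFNA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.60,1.10,H,H,train,-37.045,"written from CAS/name, neutral form"
C7,335-76-2,Perfluorodecanoic acid (PFDA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.11,1.42,H,H,test,-40.381,"written from CAS/name, neutral form"
C8,2058-94-8,Perfluoroundecanoic acid (PFUnDA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.49,1.68,H,H,train,-35.144,"written from CAS/name, neutral form"
C9,307-55-1,Perfluorododecanoic acid (PFDoA),OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,2.51,1.83,L,L,train,-25.948,"written from CAS/name, neutral form"
C10,356-02-5,3:3 Fluorotelomer carboxylic acid (3:3 FTCA),OC(=O)CCC(F)(F)C(F)(F)C(F)(F)F,2.06,2.21,L,L,train,-22.287,"written from CAS/name, neutral form"
C11,914637-49-3,5:3 Fluorotelomer carboxylic acid (5:3 FTCA),OC(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.48,1.04,H,H,train,-25.859,"written from CAS/name, neutral form"
C12,27854-30-4,6:3 Fluorotelomer carboxylic acid (6:3 FTCA),OC(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.84,0.95,H,H,train,-27.848,"written from CAS/name, neutral form"
C13,34598-33-9,8:3 Fluorotelomer carboxylic acid (8:3 FTCA),OC(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.16,1.38,H,H,train,-29.169,"written from CAS/name, neutral form"
E1,3330-15-2,"Heptafluoropropyl 1,2,2,2-tetrafluoroethyl ether (E1)",FC(F)(F)C(F)(F)C(F)(F)OC(F)C(F)(F)F,2.34,2.11,L,L,test,-18.76,"written from CAS/name, neutral form"
E2,13252-13-6,"2,3,3,3-Tetrafluoro-2-(heptafluoropropoxy)propanoic acid (HFPO-DA)",OC(=O)C(F)(OC(F)(F)C(F)(F)C(F)(F)F)C(F)(F)F,1.83,1.75,L,L,train,-24.764,"written from CAS/name, neutral form"
E3,749836-20-2,"7H-Perfluoro-4-methyl-3,6-dioxaoctanesulfonic acid (Nafion BP2)",OS(=O)(=O)C(F)(F)C(F)(F)OC(F)(C(F)(F)F)C(F)(F)OC(F)C(F)(F)F,1.90,1.70,L,L,train,-27.534,"written from CAS/name, neutral form"
E4,151772-59-7,"Perfluoro-3,6,9-trioxadecanoic acid (PFO3DoDA)",OC(=O)C(F)(F)OC(F)(F)C(F)(F)OC(F)(F)C(F)(F)OC(F)(F)F,1.67,1.66,L,L,test,-34.337,"written from CAS/name, neutral form"
S1,375-73-5,Perfluorobutanesulfonic acid (PFBS),OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.72,1.79,L,L,test,-26.738,"written from CAS/name, neutral form"
S2,355-46-4,Perfluorohexanesulfonic acid (PFHxS),OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.98,0.92,H,H,test,-27.822,"written from CAS/name, neutral form"
S3,1763-23-1,Perfluorooctanesulfonic acid (PFOS),OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.13,1.12,H,H,test,-31.682,"written from CAS/name, neutral form"
S4,757124-72-4,4:2 Fluorotelomer sulfonic acid (4:2 FTSA),OS(=O)(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)F,1.45,1.16,H,L,train,-23.829,"written from CAS/name, neutral form"
S5,59587-38-1,6:2 Fluorotelomer sulfonic acid (6:2 FTSA),OS(=O)(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,0.47,0.91,H,H,train,-28.131,"written from CAS/name, neutral form"
O1,2043-47-2,4:2 Fluorotelomer alcohol (4:2 FTOH),OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)F,,,L,L,train,-16.373,"written from CAS/name, neutral form"
O2,647-42-7,6:2 Fluorotelomer alcohol (6:2 FTOH),OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,,,L,L,test,-21.834,"written from CAS/name, neutral form"
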