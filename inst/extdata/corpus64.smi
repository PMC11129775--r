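C(C1(O[S-])N[O-])CCC1(N)C
C(C2NO)(CC(C2)C(C1(NC[NH3+])CF)(CC(C(C1(O)O)=C)OC(OOC)F)SN(N)F)C
C(C2(NCN)NNS)(C(C(C2(C([O-])(N(COC)C)C)SBr)(N(I)F)Cl)(C(=Cc(c1)cccc1)C(CC)Br)C)=C
C(C1(SCC)C(C2)CCCC2)(C(C(CC1I)([O-])C[O-])Cl)C.[K+]
c(o2)(c(c(c2-c(c3C(C([O-])N)C)c(ccc3)N)OC)Oc(c1C(C=N)O)ccc(c1C)C)[NH3+]
S=NOC(=C([S-])N(Cl)c(c1)cc(cc1S)O)C(=C(F)OC=N)C(=C)O
C(C(C5)(C(C(C5=CN)=Cc(s4)c(cc4C)S)(C)C)F)=C(CC(C3)CCC3(N)C)C(C1c(c2)cc(c(c2)O)O)C1N
c(c1N)c(oc1Cc(c2)cccn2)SOC.[Cl-]
c(o1)(cc(c1CN(C(CCS)[S-])C(C2(I)N)(C2)[O-])Cl)F
O(SCO)C(=C=NCl)OC(NC)c(c1)cccc1
c(c1C[NH3+])(nc(c(c1CC)NC(N=O)(I)C[NH3+])OO)O
c(o1)(cc(c1)C)C[O-]
N(S)(c(o2)c(c(c2OS)C([S-])N)C)c(c1O)c(c(c(c1[NH3+])C)CC)N(Cl)Cl
c(c2Nc(s3)c(cc3)S)(c(c(o2)SC)-c(c1)coc1)ON
C(#CC(C(=C(C(NC)C)C(C2O)CCC(C2)(c([nH]1)cc(c1)N)SO)C)CCl)[O-]
C(C1(C(NN)(c(n2)c(c(cc2)F)N)Cl)C)(CC(C1Br)Cl)=C
C(O[S-])(C(SN([O-])I)(C(=CBr)C(=C(S)N)C)[O-])(Cl)[NH3+]
c(c3I)(c(c(c(n3)N)[NH3+])C)N(CC([S-])[O-])C(C(C2C#C)C2)c(c1)csc1
c(c1C)(sc(c1[S-])F)C
O=NSN(NCF)CC
c([nH]2)(c(c(c2[S-])C(Cl)(C(Br)(C)C(S[S-])O)C(c(c1C)ccnc1)(ON)I)F)C
C(C1(c([nH]2)ccc2C(C3[S-])(C(C(C(C3=S)(C(N=CN)N)CC)(C)C)=NC(C)[S-])C)S)(C1[O-])([S-])N
C(C1(C(C(C(S[S-])(c(c3C)c(ccc3)N)CC)=N)C(C2)CC(C2)(S)NN)NCN)(C1=C([S-])C)=C=C=N
c(c2CC)(c(c(c(c2OC)C(C1=C)(C1(C)SOC)SS)I)[NH3+])OSC.[Cl-]
o(c2C)c(c(c2C)[O-])-c(c1)sc(c1C([NH3+])[NH3+])C
O(C(c(c3-c(c4C)cc(cc4)C)c(c(o3)OSc(o1)c(c(c1-c(o2)ccc2)C)Cl)[S-])=C)C(OI)C
c(c2Cc(o3)c(c(c3I)C=O)O)(c(sc2)C(C1N)(C1=O)ON)[O-].[Na+]
C(C1c(c2NN)cccc2)(C(C(C1=C)Br)SN)C(C(=O)N)(O)C
C(C2=O)(C(C(C2([O-])CCl)(Cc(o1)cc(c1SCF)CBr)Cl)(Cl)Br)(C(C(N=CC)(C)N=C)(C(=N)F)C=N)C=O
C(C)(C(C(SC(C3(N(O)S)[S-])(C3(C(C(=O)I)CCl)O)CC(C2O)C(CC2)=C)[O-])(Sc([nH]1)ccc1)O[NH3+])=C[NH3+]
c(c1CNN)(cc(c(c1F)F)S)O
O(N(Br)Cl)OC(OC)(OC)N(c(c2[NH3+])occ2)c(c1)[nH]c(c1)C
C(N(NCl)C([S-])(c(c1C(C)(N=S)S)c(nc(c1-c(c2)c(oc2)[NH3+])C(CC)([NH3+])CCl)Cl)C=N)=S
C(C=Cc(c1CC([S-])(C(CC)[S-])c(c2)c(cc(c2)NF)N)c([nH]c1[S-])N)(=C(NC)C#C)SCC
c(c2NC)(c(cc(c2C(C3N)(CC(C3)[O-])C)Cl)C)C(CC)c(c1)cccc1
c(c2OOCl)(c(c(nc2CC[S-])Br)SSc(c1)csc1)Cl
c(c1)c(cc(c1Cc(c2)cccc2Cl)ON)CC[O-]
S(Cc(c1C(N=C)N)c(c(s1)C)CO)C(SC(NN)(C)C(C=C[O-])I)(C(N=CC)(Cl)N)[S-]
c(c2CN)(c(cc(c2C)Cc(c1)cc(c(c1)C)[O-])C)NBr
C(N(NS)CC)(C(SBr)=C(CNC(S[S-])(c(o1)cc(c1S)[O-])S)[NH3+])(F)F.[Br-]
c(c2C(=N)Cl)(nc(c(c2Cl)Cl)N(c(c1N(C)I)c(ncc1F)CI)SO)CN
C(C2(I)[S-])(C2N)c(n1)cc(c(c1N)SCC)[S-].[Na+]
c(c1C(N)N)(sc(c1CC(C(S)C(C2)C(CC2[S-])CBr)F)C)S
C(I)C(C1C)(C(CC(C1[S-])=N)C)[NH3+]
C(OC(OCC)Cc(c2)cc(cc2)C)(I)(Nc(s1)c(c(c1)C)C)F
C(N(N)C)(C(I)([NH3+])Nc(c1)cc(cc1N)S)(SI)N
C(C=CC=CN)C(C3(c(c4)c(c(cc4)N)C)C)C(C(CC3)C(C2)CCC2)(I)C(C1)(C1)N.[Cl-]
c(n1)c(c(c(c1CC)[O-])CC)C
O(C(C1(c([nH]3)ccc3)[NH3+])(C(CC1(N(C#N)CC(c(s2)cc(c2)C(C)CN)S)C=C)SS)F)CN[NH3+]
C(C3I)(C(C(C(C3)N(C)c(c2)cccc2)(CO)[O-])=C(N)c(c1C)ccs1)OO
N([S-])(C#N)C(C(Cc(c3)occ3)(CN)C)(CC(C2=N)(C(C(C2)(Cl)c([nH]1)ccc1)N)CC[O-])SNC
N(c(c3ON(SNc(c4)cccc4)Br)c(c(s3)SC(C2(SC)C)(C2=O)O)Nc(c1)cccc1C)=C(SC)C#N
C(C(C(C#N)(CN([NH3+])[O-])OF)=C)(c(n3)c(cc(c3[S-])C(NC)c([nH]2)ccc2)C=Cc(o1)cc(c1)O)S
C(=Cc(c3CCl)c(oc3S)N(N)I)(CC(C2C)CC(C2(C)CO)(C(C(C)[NH3+])Nc(o1)c(cc1[NH3+])Br)Cl)C(F)C
o(c4CS)c(c(c4Br)-c(n2)cc(c(c2NC(C3)C3)C(CN)c(c1)c[nH]c1C=C)I)[NH3+]
N(Cl)([O-])N=NNC(C)C
C(=C(Cl)c(c1Cl)c(c(o1)C(N[NH3+])N)[NH3+])(SN)O
C(C2(S)Cl)(C(C(C2)(N)O)C)(c(o1)cc(c1C)N)[O-]
S=C(N=C(C(CCl)C(C2)CCC2)N)C(SOC(I)(N=NBr)c(c1)cc[nH]1)(F)ONC
C(C2(OC)SO)(C(C(C(C2=C([NH3+])C(OO)N)(SI)I)(CS)NBr)(c(s1)c(c(c1NO)Br)Cl)Cl)([O-])ON
C(C1([S-])N)C(C(C1)N)[NH3+]
C(C3=NC)C(C(C3C(OBr)C)ON[NH3+])(c(c2)[nH]c(c2)C)c(c1C)[nH]c(c1N)C
[nH](c1C(N(c(c3C(Cl)C)c(c([nH]3)N)N(O)C(C2)CCCC2)I)(N)Cl)c(c(c1N(I)S)C(Cl)CC)SS
O(C(CO)(CC=N)C(CC#Cc(s2)ccc2)(Cl)c(s1)ccc1)C(S[NH3+])(C(CCl)(N=S)[O-])O
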