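smiles	n_heavy	link
CC(=O)Nc1ccc(O)cc1	8	5
CC(=O)Nc1ccc(O)cc1	4	5
CC(=O)Nc1ccc(O)cc1	7	16
CC(=O)Oc1ccccc1C(=O)O	10	3
CC(=O)Oc1ccccc1C(=O)O	4	3
CC(=O)Oc1ccccc1C(=O)O	9	16
CC(=O)Oc1ccccc1C(=O)O	10	16
CC(C)Cc1ccc(C(C)C(=O)O)cc1	4	8
CC(C)Cc1ccc(C(C)C(=O)O)cc1	11	16
CC(C)Cc1ccc(C(C)C(=O)O)cc1	10	16
CC(C)Cc1ccc(C(C)C(=O)O)cc1	5	8
CN(C)CCOC(c1ccccc1)c1ccccc1	5	4
CN(C)CCOC(c1ccccc1)c1ccccc1	14	3
CN(C)CCOC(c1ccccc1)c1ccccc1	6	3
CN(C)CCOC(c1ccccc1)c1ccccc1	13	4
CN(C)CCOC(c1ccccc1)c1ccccc1	16	4
CN(C)CCOC(c1ccccc1)c1ccccc1	13	8
CN(C)CCOC(c1ccccc1)c1ccccc1	6	16
CNC(C)Cc1ccccc1	9	4
CNC(C)Cc1ccccc1	5	8
CNC(C)Cc1ccccc1	6	16
NC(=O)c1ccccc1	6	16
O=C(O)c1ccccc1O	7	16
O=C(Nc1ccccc1)c1ccccc1Cl	9	1
O=C(Nc1ccccc1)c1ccccc1Cl	7	5
O=C(Nc1ccccc1)c1ccccc1Cl	10	5
O=C(Nc1ccccc1)c1ccccc1Cl	6	16
O=C(Nc1ccccc1)c1ccccc1Cl	9	6
O=C(Nc1ccccc1)c1ccccc1Cl	7	16
CCOC(=O)c1ccccc1N	9	1
CCOC(=O)c1ccccc1N	10	3
CCOC(=O)c1ccccc1N	5	6
CCOC(=O)c1ccccc1N	7	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	14	5
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	7	1
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	7	5
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	14	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	13	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	8	5
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	16	6
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	5	14
COc1ccc(CCN)cc1	9	16
COc1ccc(CCN)cc1	8	16
CC(N)Cc1ccccc1	4	8
CC(N)Cc1ccccc1	6	16
NCCc1ccc(O)c(O)c1	8	16
CC(O)C(N)Cc1ccccc1	6	8
CC(O)C(N)Cc1ccccc1	6	16
CN(C)CCc1ccc(O)cc1	9	4
CN(C)CCc1ccc(O)cc1	5	8
CN(C)CCc1ccc(O)cc1	7	16
COc1cc2c(cc1OC)CN(C)CC2	13	16
COc1cc2c(cc1OC)CN(C)CC2	13	16
CN(C)CCc1c[nH]c2ccccc12	11	4
CN(C)CCc1c[nH]c2ccccc12	5	8
CN(C)CCc1c[nH]c2ccccc12	9	16
NCCc1c[nH]c2ccccc12	9	16
NC(Cc1c[nH]c2ccccc12)C(=O)O	6	8
NC(Cc1c[nH]c2ccccc12)C(=O)O	9	16
NC(Cc1ccc(O)cc1)C(=O)O	6	8
NC(Cc1ccc(O)cc1)C(=O)O	7	16
NC(Cc1ccccc1)C(=O)O	6	8
NC(Cc1ccccc1)C(=O)O	6	16
CSCCC(N)C(=O)O	7	4
CC(=O)Nc1ccc(S(N)(=O)=O)cc1	11	5
CC(=O)Nc1ccc(S(N)(=O)=O)cc1	4	5
CC(=O)Nc1ccc(S(N)(=O)=O)cc1	10	16
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	10	12
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	7	5
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	11	5
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	6	14
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	10	12
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	7	5
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	11	5
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	6	14
CCN(CC)CCNC(=O)c1ccc(N)cc1	8	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	9	1
CCN(CC)CCNC(=O)c1ccc(N)cc1	15	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	5	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	12	4
CCN(CC)CCNC(=O)c1ccc(N)cc1	7	4
CCN(CC)CCNC(=O)c1ccc(N)cc1	10	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	10	6
CCN(CC)CCNC(=O)c1ccc(N)cc1	7	16
CCN(CC)CCOC(=O)c1ccc(N)cc1	8	3
CCN(CC)CCOC(=O)c1ccc(N)cc1	9	1
CCN(CC)CCOC(=O)c1ccc(N)cc1	7	4
CCN(CC)CCOC(=O)c1ccc(N)cc1	10	3
CCN(CC)CCOC(=O)c1ccc(N)cc1	15	5
CCN(CC)CCOC(=O)c1ccc(N)cc1	5	5
CCN(CC)CCOC(=O)c1ccc(N)cc1	12	4
CCN(CC)CCOC(=O)c1ccc(N)cc1	10	6
CCN(CC)CCOC(=O)c1ccc(N)cc1	7	16
CCCCOC(=O)c1ccc(N)cc1	5	3
CCCCOC(=O)c1ccc(N)cc1	9	1
CCCCOC(=O)c1ccc(N)cc1	4	4
CCCCOC(=O)c1ccc(N)cc1	10	3
CCCCOC(=O)c1ccc(N)cc1	7	6
CCCCOC(=O)c1ccc(N)cc1	7	16
CN1CCCC1c1cccnc1	6	13
CN1CCCC1c1cccnc1	6	16
O=C(O)c1cccnc1	6	16
NC(=O)c1cccnc1	6	16
OCc1ccccc1	6	16
OCCc1ccccc1	6	16
COc1ccccc1OCC(O)CNC(C)C	9	3
COc1ccccc1OCC(O)CNC(C)C	8	4
COc1ccccc1OCC(O)CNC(C)C	15	16
COc1ccccc1OCC(O)CNC(C)C	8	16
COc1ccccc1OCC(O)CNC(C)C	9	3
COc1ccccc1OCC(O)CNC(C)C	13	4
COc1ccccc1OCC(O)CNC(C)C	4	5
COc1ccccc1OCC(O)CNC(C)C	14	5
CC(C)NCC(O)COc1cccc2ccccc12	8	4
CC(C)NCC(O)COc1cccc2ccccc12	11	3
CC(C)NCC(O)COc1cccc2ccccc12	9	3
CC(C)NCC(O)COc1cccc2ccccc12	10	16
CC(C)NCC(O)COc1cccc2ccccc12	16	5
CC(C)NCC(O)COc1cccc2ccccc12	4	5
CC(C)NCC(O)COc1cccc2ccccc12	15	4
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	8	4
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	11	3
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	9	3
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	10	16
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	16	5
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	4	5
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	15	4
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	15	16
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	4	8
COCCc1ccc(OCC(O)CNC(C)C)cc1	17	4
COCCc1ccc(OCC(O)CNC(C)C)cc1	11	3
COCCc1ccc(OCC(O)CNC(C)C)cc1	8	4
COCCc1ccc(OCC(O)CNC(C)C)cc1	10	16
COCCc1ccc(OCC(O)CNC(C)C)cc1	9	3
COCCc1ccc(OCC(O)CNC(C)C)cc1	15	4
COCCc1ccc(OCC(O)CNC(C)C)cc1	4	5
COCCc1ccc(OCC(O)CNC(C)C)cc1	16	5
COCCc1ccc(OCC(O)CNC(C)C)cc1	4	8
COCCc1ccc(OCC(O)CNC(C)C)cc1	15	16
CC(C)NCC(O)c1ccc(O)c(O)c1	12	5
CC(C)NCC(O)c1ccc(O)c(O)c1	4	5
CC(C)NCC(O)c1ccc(O)c(O)c1	11	4
CC(C)NCC(O)c1ccc(O)c(O)c1	7	8
CC(C)NCC(O)c1ccc(O)c(O)c1	8	16
CNCC(O)c1ccc(O)c(O)c1	11	4
CNCC(O)c1ccc(O)c(O)c1	5	8
CNCC(O)c1ccc(O)c(O)c1	8	16
NCC(O)c1ccc(O)c(O)c1	4	8
NCC(O)c1ccc(O)c(O)c1	8	16
NCC(O)c1ccc(O)cc1	4	8
NCC(O)c1ccc(O)cc1	7	16
CNC(C)C(O)c1ccccc1	10	4
CNC(C)C(O)c1ccccc1	6	8
CNC(C)C(O)c1ccccc1	6	16
O=C(O)Cc1ccccc1	4	8
O=C(O)Cc1ccccc1	6	16
O=C(O)CCc1ccccc1	5	8
O=C(O)CCc1ccccc1	6	16
CC(=O)Nc1ccccc1	7	5
CC(=O)Nc1ccccc1	4	5
CC(=O)Nc1ccccc1	6	16
CC(=O)c1ccccc1	6	16
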