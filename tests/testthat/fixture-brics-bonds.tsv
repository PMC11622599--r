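smiles	i	j	la	lb
CC(=O)Nc1ccc(O)cc1	1	3	1	5
CC(=O)Nc1ccc(O)cc1	3	4	5	16
CC(=O)Oc1ccccc1C(=O)O	1	3	1	3
CC(=O)Oc1ccccc1C(=O)O	3	4	3	16
CC(=O)Oc1ccccc1C(=O)O	10	9	6	16
CC(C)Cc1ccc(C(C)C(=O)O)cc1	3	4	8	16
CC(C)Cc1ccc(C(C)C(=O)O)cc1	8	7	8	16
CN(C)CCOC(c1ccccc1)c1ccccc1	5	4	3	4
CN(C)CCOC(c1ccccc1)c1ccccc1	5	6	3	4
CN(C)CCOC(c1ccccc1)c1ccccc1	3	1	4	5
CN(C)CCOC(c1ccccc1)c1ccccc1	6	7	8	16
CN(C)CCOC(c1ccccc1)c1ccccc1	6	13	8	16
CNC(C)Cc1ccccc1	2	1	4	5
CNC(C)Cc1ccccc1	4	5	8	16
NC(=O)c1ccccc1	1	3	6	16
O=C(O)c1ccccc1O	1	3	6	16
O=C(Nc1ccccc1)c1ccccc1Cl	1	2	1	5
O=C(Nc1ccccc1)c1ccccc1Cl	2	3	5	16
O=C(Nc1ccccc1)c1ccccc1Cl	1	9	6	16
CCOC(=O)c1ccccc1N	3	2	1	3
CCOC(=O)c1ccccc1N	2	1	3	4
CCOC(=O)c1ccccc1N	3	5	6	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	10	9	1	5
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	4	5	5	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	9	8	5	16
CN1CCN(c2ccc(NC(=O)c3ccco3)cc2)CC1	10	12	6	14
COc1ccc(CCN)cc1	1	2	3	16
COc1ccc(CCN)cc1	6	5	8	16
CC(N)Cc1ccccc1	3	4	8	16
NCCc1ccc(O)c(O)c1	2	3	8	16
CC(O)C(N)Cc1ccccc1	5	6	8	16
CN(C)CCc1ccc(O)cc1	3	1	4	5
CN(C)CCc1ccc(O)cc1	4	5	8	16
COc1cc2c(cc1OC)CN(C)CC2	1	2	3	16
COc1cc2c(cc1OC)CN(C)CC2	8	7	3	16
CN(C)CCc1c[nH]c2ccccc12	3	1	4	5
CN(C)CCc1c[nH]c2ccccc12	4	5	8	16
NCCc1c[nH]c2ccccc12	2	3	8	16
NC(Cc1c[nH]c2ccccc12)C(=O)O	2	3	8	16
NC(Cc1ccc(O)cc1)C(=O)O	2	3	8	16
NC(Cc1ccccc1)C(=O)O	2	3	8	16
CSCCC(N)C(=O)O	2	1	4	11
CC(=O)Nc1ccc(S(N)(=O)=O)cc1	1	3	1	5
CC(=O)Nc1ccc(S(N)(=O)=O)cc1	3	4	5	16
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	8	5	5	12
Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1	8	9	5	14
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	8	5	5	12
Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1	8	9	5	14
CCN(CC)CCNC(=O)c1ccc(N)cc1	8	7	1	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	1	2	4	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	3	2	4	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	5	2	4	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	6	7	4	5
CCN(CC)CCNC(=O)c1ccc(N)cc1	8	10	6	16
CCN(CC)CCOC(=O)c1ccc(N)cc1	8	7	1	3
CCN(CC)CCOC(=O)c1ccc(N)cc1	7	6	3	4
CCN(CC)CCOC(=O)c1ccc(N)cc1	1	2	4	5
CCN(CC)CCOC(=O)c1ccc(N)cc1	3	2	4	5
CCN(CC)CCOC(=O)c1ccc(N)cc1	5	2	4	5
CCN(CC)CCOC(=O)c1ccc(N)cc1	8	10	6	16
CCCCOC(=O)c1ccc(N)cc1	5	4	1	3
CCCCOC(=O)c1ccc(N)cc1	4	3	3	4
CCCCOC(=O)c1ccc(N)cc1	5	7	6	16
CN1CCCC1c1cccnc1	5	6	13	16
O=C(O)c1cccnc1	1	3	6	16
NC(=O)c1cccnc1	1	3	6	16
OCc1ccccc1	1	2	8	16
OCCc1ccccc1	2	3	8	16
COc1ccccc1OCC(O)CNC(C)C	8	9	3	4
COc1ccccc1OCC(O)CNC(C)C	1	2	3	16
COc1ccccc1OCC(O)CNC(C)C	8	7	3	16
COc1ccccc1OCC(O)CNC(C)C	12	13	4	5
COc1ccccc1OCC(O)CNC(C)C	14	13	4	5
CC(C)NCC(O)COc1cccc2ccccc12	8	7	3	4
CC(C)NCC(O)COc1cccc2ccccc12	8	9	3	16
CC(C)NCC(O)COc1cccc2ccccc12	1	3	4	5
CC(C)NCC(O)COc1cccc2ccccc12	4	3	4	5
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	8	7	3	4
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	8	9	3	16
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	1	3	4	5
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	4	3	4	5
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	13	12	8	16
COCCc1ccc(OCC(O)CNC(C)C)cc1	1	2	3	4
COCCc1ccc(OCC(O)CNC(C)C)cc1	8	9	3	4
COCCc1ccc(OCC(O)CNC(C)C)cc1	8	7	3	16
COCCc1ccc(OCC(O)CNC(C)C)cc1	12	13	4	5
COCCc1ccc(OCC(O)CNC(C)C)cc1	14	13	4	5
COCCc1ccc(OCC(O)CNC(C)C)cc1	3	4	8	16
CC(C)NCC(O)c1ccc(O)c(O)c1	1	3	4	5
CC(C)NCC(O)c1ccc(O)c(O)c1	4	3	4	5
CC(C)NCC(O)c1ccc(O)c(O)c1	5	7	8	16
CNCC(O)c1ccc(O)c(O)c1	2	1	4	5
CNCC(O)c1ccc(O)c(O)c1	3	5	8	16
NCC(O)c1ccc(O)c(O)c1	2	4	8	16
NCC(O)c1ccc(O)cc1	2	4	8	16
CNC(C)C(O)c1ccccc1	2	1	4	5
CNC(C)C(O)c1ccccc1	4	6	8	16
O=C(O)Cc1ccccc1	3	4	8	16
O=C(O)CCc1ccccc1	4	5	8	16
CC(=O)Nc1ccccc1	1	3	1	5
CC(=O)Nc1ccccc1	3	4	5	16
CC(=O)c1ccccc1	1	3	6	16
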