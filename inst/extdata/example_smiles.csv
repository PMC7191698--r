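drug_id,smiles
aspirin,CC(=O)OC1=CC=CC=C1C(=O)O
ibuprofen,CC(C)CC1=CC=C(C=C1)C(C)C(=O)O
naproxen,COC1=CC2=CC(=CC=C2C=C1)C(C)C(=O)O
caffeine,CN1C=NC2=C1C(=O)N(C)C(=O)N2C
fluoxetine,CNCCC(OC1=CC=C(C=C1)C(F)(F)F)C2=CC=CC=C2
sertraline,CNC1CCC(C2=CC=CC=C12)C3=CC(=C(C=C3)Cl)Cl
metoprolol,CC(C)NCC(O)COC1=CC=C(CCOC)C=C1
propranolol,CC(C)NCC(O)COC1=CC=CC2=CC=CC=C12
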