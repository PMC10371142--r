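id,smiles,role,name
PIMP,CC(C)OP(C)(=O)ON1C(=O)c2ccccc2C1=O,OP,phthalimidyl isopropyl methylphosphonate (sarin surrogate)
NEMP,CCOP(C)(=O)Oc1ccc(cc1)[N+](=O)[O-],OP,4-nitrophenyl ethyl methylphosphonate (VX surrogate)
PXN,CCOP(=O)(OCC)Oc1ccc(cc1)[N+](=O)[O-],OP,paraoxon (parathion metabolite)
DFP,CC(C)OP(=O)(F)OC(C)C,OP,diisopropylphosphofluoridate
GV,CN(C)CCOP(=O)(F)N(C)C,OP,"2-[dimethylamino(fluoro)phosphoryl]oxy-N,N-dimethylethanamine"
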