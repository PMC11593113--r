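# Motif catalogue: one pattern per line, dash-separated positions,
# "/" alternation, "X" wildcard, "p" marks the phospho-acceptor token.
# Curated kinase-substrate context motifs reported for eukaryotic-like
# prokaryotic kinases and common eukaryotic kinase families; edit freely —
# these are user data, not code.
R-X-X-pS/pT-L/I/V      # PKA/PknB-like basophilic + hydrophobic
R-R-X-pS/pT            # basophilic (PKA-like)
L-X-R-X-X-pS/pT        # extended basophilic
R/K-X-X-pS/pT/pY       # basophilic -3
R/K-X-pS/pT            # basophilic -2
pS/pT-P                # proline-directed (CDK/MAPK-like)
pS/pT-P-X-R/K          # proline-directed + basic
pS/pT/pY-X-X-D/E       # acidophilic +3 (CK2-like)
pS/pT-X-X-E            # acidophilic
pS/pT-X-L/I/V          # hydrophobic +2
pS/pT-F                # aromatic +1
G-pH-A                 # Gly-pHis-Ala (3-pHis antibody-like context)
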