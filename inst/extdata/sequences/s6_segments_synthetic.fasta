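>rNav1.4_DIII_S6_synthetic start=1271 note=invented sequence, identified residues I1284/I1288 at true numbering
GLFYWTLLSMQAGIVSLIANLVQAVGMDLF
>hNav1.7_DIII_S6_synthetic start=1440 note=invented sequence, identified residues I1453/I1457 at true numbering
TLFYWTLLSLEATIVSLIASLVEAVTLELF
>rNav1.4_DIV_S6_synthetic start=1576 note=invented sequence, identified residues I1587/L1591 at true numbering
MICLFQIATFKIWMDLMYSAVDSRGYEEQP
>hNav1.7_DIV_S6_synthetic start=1745 note=invented sequence, identified residues I1756/L1760 at true numbering
MICLFRIATFTIWMDLMYAAVDARGYDDRQ
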