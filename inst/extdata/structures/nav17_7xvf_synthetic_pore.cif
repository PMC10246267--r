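data_nav17_m11_pore_stand_in_cf_7xvf
# SYNTHETIC STAND-IN GEOMETRY; NOT DEPOSITED COORDINATES
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_comp_id
_atom_site.auth_asym_id
_atom_site.auth_seq_id
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
ATOM 1 C CA GLY A 9001 9.000 0.000 -10.000
ATOM 2 C CA GLY A 9002 6.364 6.364 -10.000
ATOM 3 C CA GLY B 9001 0.000 9.000 -10.000
ATOM 4 C CA GLY B 9002 -6.364 6.364 -10.000
ATOM 5 C CA GLY C 9001 -9.000 0.000 -10.000
ATOM 6 C CA GLY C 9002 -6.364 -6.364 -10.000
ATOM 7 C CA GLY D 9001 -0.000 -9.000 -10.000
ATOM 8 C CA GLY D 9002 6.364 -6.364 -10.000
ATOM 9 C CA GLY A 9003 7.500 0.000 -8.000
ATOM 10 C CA GLY A 9004 5.303 5.303 -8.000
ATOM 11 C CA GLY B 9003 0.000 7.500 -8.000
ATOM 12 C CA GLY B 9004 -5.303 5.303 -8.000
ATOM 13 C CA GLY C 9003 -7.500 0.000 -8.000
ATOM 14 C CA GLY C 9004 -5.303 -5.303 -8.000
ATOM 15 C CA GLY D 9003 -0.000 -7.500 -8.000
ATOM 16 C CA GLY D 9004 5.303 -5.303 -8.000
ATOM 17 C CA ALA A 402 5.020 5.020 -5.400
ATOM 18 C CB ALA A 402 3.182 3.182 -5.400
ATOM 19 C CA LEU B 968 -5.020 5.020 -5.400
ATOM 20 C CB LEU B 968 -3.182 3.182 -5.400
ATOM 21 C CA ILE C 1457 -5.020 -5.020 -5.400
ATOM 22 C CB ILE C 1457 -3.182 -3.182 -5.400
ATOM 23 C CA LEU D 1760 5.020 -5.020 -5.400
ATOM 24 C CB LEU D 1760 3.182 -3.182 -5.400
ATOM 25 C CA GLY A 9005 5.543 2.296 -2.700
ATOM 26 C CA GLY A 9006 2.296 5.543 -2.700
ATOM 27 C CA GLY B 9005 -2.296 5.543 -2.700
ATOM 28 C CA GLY B 9006 -5.543 2.296 -2.700
ATOM 29 C CA GLY C 9005 -5.543 -2.296 -2.700
ATOM 30 C CA GLY C 9006 -2.296 -5.543 -2.700
ATOM 31 C CA GLY D 9005 2.296 -5.543 -2.700
ATOM 32 C CA GLY D 9006 5.543 -2.296 -2.700
ATOM 33 C CA LEU A 398 4.667 4.667 0.000
ATOM 34 C CB LEU A 398 2.828 2.828 0.000
ATOM 35 C CA LEU B 964 -4.667 4.667 0.000
ATOM 36 C CB LEU B 964 -2.828 2.828 0.000
ATOM 37 C CA ILE C 1453 -4.667 -4.667 0.000
ATOM 38 C CB ILE C 1453 -2.828 -2.828 0.000
ATOM 39 C CA ILE D 1756 4.667 -4.667 0.000
ATOM 40 C CB ILE D 1756 2.828 -2.828 0.000
ATOM 41 C CA GLY A 9007 6.401 1.129 3.000
ATOM 42 C CA GLY A 9008 3.728 5.324 3.000
ATOM 43 C CA GLY B 9007 -1.129 6.401 3.000
ATOM 44 C CA GLY B 9008 -5.324 3.728 3.000
ATOM 45 C CA GLY C 9007 -6.401 -1.129 3.000
ATOM 46 C CA GLY C 9008 -3.728 -5.324 3.000
ATOM 47 C CA GLY D 9007 1.129 -6.401 3.000
ATOM 48 C CA GLY D 9008 5.324 -3.728 3.000
ATOM 49 C CA GLY A 9009 7.000 0.000 6.000
ATOM 50 C CA GLY A 9010 4.950 4.950 6.000
ATOM 51 C CA GLY B 9009 0.000 7.000 6.000
ATOM 52 C CA GLY B 9010 -4.950 4.950 6.000
ATOM 53 C CA GLY C 9009 -7.000 0.000 6.000
ATOM 54 C CA GLY C 9010 -4.950 -4.950 6.000
ATOM 55 C CA GLY D 9009 -0.000 -7.000 6.000
ATOM 56 C CA GLY D 9010 4.950 -4.950 6.000
ATOM 57 C CA GLY A 9011 6.062 3.500 9.000
ATOM 58 C CA GLY A 9012 1.812 6.761 9.000
ATOM 59 C CA GLY B 9011 -3.500 6.062 9.000
ATOM 60 C CA GLY B 9012 -6.761 1.812 9.000
ATOM 61 C CA GLY C 9011 -6.062 -3.500 9.000
ATOM 62 C CA GLY C 9012 -1.812 -6.761 9.000
ATOM 63 C CA GLY D 9011 3.500 -6.062 9.000
ATOM 64 C CA GLY D 9012 6.761 -1.812 9.000
ATOM 65 C CA GLY A 9013 6.500 0.000 12.000
ATOM 66 C CA GLY A 9014 4.596 4.596 12.000
ATOM 67 C CA GLY B 9013 0.000 6.500 12.000
ATOM 68 C CA GLY B 9014 -4.596 4.596 12.000
ATOM 69 C CA GLY C 9013 -6.500 0.000 12.000
ATOM 70 C CA GLY C 9014 -4.596 -4.596 12.000
ATOM 71 C CA GLY D 9013 -0.000 -6.500 12.000
ATOM 72 C CA GLY D 9014 4.596 -4.596 12.000
ATOM 73 C CA GLY A 9015 4.733 1.268 15.000
ATOM 74 C CA GLY A 9016 2.450 4.244 15.000
ATOM 75 C CA GLY B 9015 -1.268 4.733 15.000
ATOM 76 C CA GLY B 9016 -4.244 2.450 15.000
ATOM 77 C CA GLY C 9015 -4.733 -1.268 15.000
ATOM 78 C CA GLY C 9016 -2.450 -4.244 15.000
ATOM 79 C CA GLY D 9015 1.268 -4.733 15.000
ATOM 80 C CA GLY D 9016 4.244 -2.450 15.000
ATOM 81 C CA GLY A 9016 2.450 4.244 16.500
ATOM 82 C CA GLY A 9017 -1.268 4.733 16.500
ATOM 83 C CA GLY B 9016 -4.244 2.450 16.500
ATOM 84 C CA GLY B 9017 -4.733 -1.268 16.500
ATOM 85 C CA GLY C 9016 -2.450 -4.244 16.500
ATOM 86 C CA GLY C 9017 1.268 -4.733 16.500
ATOM 87 C CA GLY D 9016 4.244 -2.450 16.500
ATOM 88 C CA GLY D 9017 4.733 1.268 16.500
ATOM 89 C CA GLY A 9017 7.000 0.000 19.000
ATOM 90 C CA GLY A 9018 4.950 4.950 19.000
ATOM 91 C CA GLY B 9017 0.000 7.000 19.000
ATOM 92 C CA GLY B 9018 -4.950 4.950 19.000
ATOM 93 C CA GLY C 9017 -7.000 0.000 19.000
ATOM 94 C CA GLY C 9018 -4.950 -4.950 19.000
ATOM 95 C CA GLY D 9017 -0.000 -7.000 19.000
ATOM 96 C CA GLY D 9018 4.950 -4.950 19.000
ATOM 97 C CA GLY A 9019 10.000 0.000 22.000
ATOM 98 C CA GLY A 9020 7.071 7.071 22.000
ATOM 99 C CA GLY B 9019 0.000 10.000 22.000
ATOM 100 C CA GLY B 9020 -7.071 7.071 22.000
ATOM 101 C CA GLY C 9019 -10.000 0.000 22.000
ATOM 102 C CA GLY C 9020 -7.071 -7.071 22.000
ATOM 103 C CA GLY D 9019 -0.000 -10.000 22.000
ATOM 104 C CA GLY D 9020 7.071 -7.071 22.000
#
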