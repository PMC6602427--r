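data_toy_complex
_entry.id 'toy_complex'

_cell.entry_id 'toy_complex'
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id 'toy_complex'
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
A polymer
B polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
A polypeptide(L) A ?
B polypeptide(L) B ?



loop_
_chem_comp.id
_chem_comp.type
ALA .
LYS .
PHE .

loop_
_struct_asym.id
_struct_asym.entity_id
Axp A
Bxp B



loop_
_atom_type.symbol
C
N
O


loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_asym_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA Axp A . ? 0.049 0.014 0.03 1 0 ? 1 A 1
ATOM 2 C CA . ALA Axp A . ? 1.448 -0.02 -0.012 1 0 ? 1 A 1
ATOM 3 C C . ALA Axp A . ? 1.971 1.471 0.026 1 0 ? 1 A 1
ATOM 4 O O . ALA Axp A . ? 2.867 1.789 -0.78 1 0 ? 1 A 1
ATOM 5 C CB . ALA Axp A . ? 1.943 -0.672 -1.209 1 0 ? 1 A 1
ATOM 6 N N . PHE Axp A . ? 1.498 2.226 0.851 1 0 ? 2 A 1
ATOM 7 C CA . PHE Axp A . ? 1.892 3.669 0.926 1 0 ? 2 A 1
ATOM 8 C C . PHE Axp A . ? 1.825 4.372 -0.341 1 0 ? 2 A 1
ATOM 9 O O . PHE Axp A . ? 2.667 5.105 -0.773 1 0 ? 2 A 1
ATOM 10 C CB . PHE Axp A . ? 3.335 3.73 1.496 1 0 ? 2 A 1
ATOM 11 C CG . PHE Axp A . ? 3.419 3.039 2.831 1 0 ? 2 A 1
ATOM 12 C CD1 . PHE Axp A . ? 3.707 1.689 2.894 1 0 ? 2 A 1
ATOM 13 C CD2 . PHE Axp A . ? 3.213 3.756 3.995 1 0 ? 2 A 1
ATOM 14 C CE1 . PHE Axp A . ? 3.783 1.055 4.12 1 0 ? 2 A 1
ATOM 15 C CE2 . PHE Axp A . ? 3.287 3.121 5.22 1 0 ? 2 A 1
ATOM 16 C CZ . PHE Axp A . ? 3.574 1.77 5.282 1 0 ? 2 A 1
ATOM 17 N N . ALA Axp A . ? 0.596 4.233 -1.015 1 0 ? 3 A 1
ATOM 18 C CA . ALA Axp A . ? 0.354 4.823 -2.29 1 0 ? 3 A 1
ATOM 19 C C . ALA Axp A . ? 1.465 4.416 -3.308 1 0 ? 3 A 1
ATOM 20 O O . ALA Axp A . ? 1.943 5.263 -4.03 1 0 ? 3 A 1
ATOM 21 C CB . ALA Axp A . ? 0.405 6.356 -2.127 1 0 ? 3 A 1
ATOM 22 N N . ALA Axp A . ? 1.688 3.188 -3.427 1 0 ? 4 A 1
ATOM 23 C CA . ALA Axp A . ? 2.729 2.643 -4.387 1 0 ? 4 A 1
ATOM 24 C C . ALA Axp A . ? 4.028 3.34 -4.171 1 0 ? 4 A 1
ATOM 25 O O . ALA Axp A . ? 4.771 3.781 -5.104 1 0 ? 4 A 1
ATOM 26 C CB . ALA Axp A . ? 2.244 2.918 -5.808 1 0 ? 4 A 1
ATOM 27 N N . LYS Bxp B . ? -0.031 -0.039 4.773 1 0 ? 1 B 1
ATOM 28 C CA . LYS Bxp B . ? 1.458 -0.038 4.764 1 0 ? 1 B 1
ATOM 29 C C . LYS Bxp B . ? 2.036 -1.396 4.763 1 0 ? 1 B 1
ATOM 30 O O . LYS Bxp B . ? 2.929 -1.773 5.548 1 0 ? 1 B 1
ATOM 31 C CB . LYS Bxp B . ? 1.948 0.736 6.01 1 0 ? 1 B 1
ATOM 32 C CG . LYS Bxp B . ? 1.486 2.194 5.948 1 0 ? 1 B 1
ATOM 33 C CD . LYS Bxp B . ? 1.975 2.937 7.194 1 0 ? 1 B 1
ATOM 34 C CE . LYS Bxp B . ? 1.513 4.394 7.133 1 0 ? 1 B 1
ATOM 35 N NZ . LYS Bxp B . ? 1.983 5.108 8.328 1 0 ? 1 B 1
ATOM 36 N N . ALA Bxp B . ? 1.485 -2.228 3.91 1 0 ? 2 B 1
ATOM 37 C CA . ALA Bxp B . ? 1.905 -3.616 3.75 1 0 ? 2 B 1
ATOM 38 C C . ALA Bxp B . ? 1.776 -4.399 5.181 1 0 ? 2 B 1
ATOM 39 O O . ALA Bxp B . ? 2.684 -5.043 5.55 1 0 ? 2 B 1
ATOM 40 C CB . ALA Bxp B . ? 3.367 -3.69 3.391 1 0 ? 2 B 1
ATOM 41 N N . ALA Bxp B . ? 0.608 -4.199 5.767 1 0 ? 3 B 1
ATOM 42 C CA . ALA Bxp B . ? 0.39 -4.798 7.085 1 0 ? 3 B 1
ATOM 43 C C . ALA Bxp B . ? 1.472 -4.488 8.143 1 0 ? 3 B 1
ATOM 44 O O . ALA Bxp B . ? 1.995 -5.263 8.782 1 0 ? 3 B 1
ATOM 45 C CB . ALA Bxp B . ? 0.373 -6.39 6.9 1 0 ? 3 B 1
ATOM 46 N N . ALA Bxp B . ? 1.736 -3.16 8.165 1 0 ? 4 B 1
ATOM 47 C CA . ALA Bxp B . ? 2.717 -2.647 9.11 1 0 ? 4 B 1
ATOM 48 C C . ALA Bxp B . ? 4.071 -3.297 8.874 1 0 ? 4 B 1
ATOM 49 O O . ALA Bxp B . ? 4.734 -3.78 9.887 1 0 ? 4 B 1
ATOM 50 C CB . ALA Bxp B . ? 2.306 -2.89 10.515 1 0 ? 4 B 1
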