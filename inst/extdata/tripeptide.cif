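data_tripeptide
_entry.id tripeptide

_cell.entry_id tripeptide
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id tripeptide
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
A polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
A polypeptide(L) A ?



loop_
_chem_comp.id
_chem_comp.type
ALA .

loop_
_struct_asym.id
_struct_asym.entity_id
Axp A



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
ATOM 1 N N . ALA Axp A . ? 0 0 0 1 0 ? 1 A 1
ATOM 2 C CA . ALA Axp A . ? 1.458 0 0 1 0 ? 1 A 1
ATOM 3 C C . ALA Axp A . ? 2.009 1.422 0 1 0 ? 1 A 1
ATOM 4 O O . ALA Axp A . ? 2.91 1.749 -0.773 1 0 ? 1 A 1
ATOM 5 N N . ALA Axp A . ? 1.463 2.263 0.872 1 0 ? 2 A 1
ATOM 6 C CA . ALA Axp A . ? 1.899 3.65 0.974 1 0 ? 2 A 1
ATOM 7 C C . ALA Axp A . ? 1.768 4.37 -0.364 1 0 ? 2 A 1
ATOM 8 O O . ALA Axp A . ? 2.689 5.059 -0.802 1 0 ? 2 A 1
ATOM 9 N N . ALA Axp A . ? 0.618 4.205 -1.008 1 0 ? 3 A 1
ATOM 10 C CA . ALA Axp A . ? 0.364 4.838 -2.297 1 0 ? 3 A 1
ATOM 11 C C . ALA Axp A . ? 1.421 4.443 -3.323 1 0 ? 3 A 1
ATOM 12 O O . ALA Axp A . ? 1.961 5.294 -4.03 1 0 ? 3 A 1
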