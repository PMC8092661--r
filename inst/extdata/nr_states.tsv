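# Desk-scale nuclear-receptor character fixture: RxxxE motif state
# (sequence evidence; canonical motif only, degraded variants count as
# absent) and pi-turn state (structure evidence where a crystal structure
# or an explicit published inference exists; unknown otherwise).
# provenance: structure | sequence-only | inferred | unknown
taxon	motif_variant	motif_state	pi_turn	provenance
Ctenophora_NR2A	none	absent	absent	sequence-only
SpNR2_Amphimedon	none	absent	absent	sequence-only
HNF4_Trichoplax	RxxxE	present	present	inferred
HNF4_Nematostella	RxxxE	present	present	inferred
HNF4_human	RxxxE	present	present	structure
SpNR1_P1	RxxxE	present	present	inferred
SpNR1_P2	RxxxE	present	present	inferred
SpNR1_P3	none	absent	absent	sequence-only
SpNR1_P4	RxxxE	present	present	inferred
RXR_human	RxxxE	present	present	structure
USP_Drosophila	RxxxE	present	present	structure
COUPTF2_human	RxxxE	present	absent	structure
EAR2_human	RxxxE	present	unknown	unknown
Hydractinia_NR2F	none	absent	absent	sequence-only
PNR_human	RxxxE	present	absent	structure
TLX_human	QxxxE	absent	absent	sequence-only
FAX1_Drosophila	none	absent	absent	sequence-only
Trichoplax_21656	unknown	unknown	unknown	unknown
ER_human	none	absent	absent	structure
NR3_Trichoplax	RxxxE	present	unknown	unknown
TR_human	none	absent	absent	structure
RAR_human	none	absent	absent	structure
NR4A1_human	none	absent	absent	sequence-only
SF1_human	none	absent	absent	structure
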