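# Bundled cis-element motif table (IUPAC nucleotide consensi).
# The HSE core is the heat-shock element core reported for this family's
# promoters; the remaining entries are canonical published consensi for
# the named elements. The table is user-replaceable data: element tallies
# depend entirely on the motif library used.
name	sequence	category	response
HSE	AAAAAATTTC	stress	heat
TC-rich	ATTTTCTTCA	stress	defense
LTR	CCGAAA	stress	low-temperature
MBS	CAACTG	stress	drought
ABRE	ACGTG	hormone	ABA
TCA-element	CCATCTTTTT	hormone	SA
TGA-element	AACGAC	hormone	IAA
GARE-motif	TCTGTTG	hormone	GA
CGTCA-motif	CGTCA	hormone	MeJA
ERE	ATTTCAAA	hormone	ethylene
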