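protein	gene	accession_human	accession_mouse	compartment	peptide	precursor_mz	precursor_charge	transitions
prelamin-A/C	LMNA	P02545	P48678	nuclear	EGDLIAAQAR	522.278	2	y7+,y6+,y5+,y4+,b3+
prelamin-A/C	LMNA	P02545	P48678	nuclear	LADALQELR	514.790	2	y8+,y7+,y6+,y5+,b2+
nucleophosmin	NPM	P06748	P13084	nuclear	VDNDENEHQLSLR	784.869	2	y6+,y5+,y4+,y3+,y1+
ATP synthase subunit alpha, mitochondrial	ATP5F1A	P25705	Q03265	mitochondrial	ILGADTSVDLEETGR	788.397	2	y13+,y11+,y10+,y9+,y7+
ATP synthase subunit alpha, mitochondrial	ATP5F1A	P25705	Q03265	mitochondrial	VLSIGDGIAR	500.793	2	y8+,y7+,y6+,y4+
ATP synthase subunit alpha, mitochondrial	ATP5F1A	P25705	Q03265	mitochondrial	TGAIVDVPVGEELLGR	812.949	2	y12+,y11+,y10+,y9+,b3+
carbamoyl-phosphate synthase [ammonia], mitochondrial	CPS1	P31327	Q8C196	mitochondrial	IALGIPLPEIK	582.373	2	y6+,y4+,y2+,b2+,b4+
NDUFAF4	NDUFAF4	Q9P032	Q9D6J6	mitochondrial	EQISLYPEVK	603.324	2	y7+,y5+,y4+,y2+,b2+
NDUFAF4	NDUFAF4	Q9P032	Q9D6J6	mitochondrial	IMQEYQLEQK	437.220	3	y4+,y3+,y2+
METK2	MAT2A	Q9Y5K3	Q9DBP5	cytosolic	TQVTVQYMQDR	684.832	2	y9+,y8+,y6+,b2+
METK2	MAT2A	Q9Y5K3	Q9DBP5	cytosolic	YLDEDTIYHLQPSGR	903.936	2	y8+,y7+,y6+,y5+,y4+
METK2	MAT2A	Q9Y5K3	Q9DBP5	cytosolic	FVIGGPQGDAGLTGR	722.880	2	y13+,y12+,y8+,y6+,b2+
heat shock protein HSP 90-beta	HSP90AB1	P08238	P11499	cytosolic	YHTSQSGDEMTSLSEYVSR	726.320	3	y9+,y8+,y7+,y6+,b9+
heat shock protein HSP 90-beta	HSP90AB1	P08238	P11499	cytosolic	HLEINPDHPIVETLR	594.989	3	y7+,y5+,b2+,b5+,b7+
adenosylhomocysteinase	AHCY	P23526	Q8BWF0	cytosolic	VPAINVNDSVTK	628.846	2	y10+,y9+,y8+,b2+,b3+
adenosylhomocysteinase	AHCY	P23526	Q8BWF0	cytosolic	IILLAEGR	442.782	2	y6+,y5+,y4+,y2+,b2+
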