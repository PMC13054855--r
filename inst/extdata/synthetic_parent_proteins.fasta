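>LMNA_synthetic synthetic parent scaffold for LMNA marker peptides
MSTELAQVKEGDLIAAQARTGQVESALRLADALQELRDLSVGETANREGGLSTAAPK
>NPM_synthetic synthetic parent scaffold for NPM marker peptides
MSTELAQVKVDNDENEHQLSLRTGQVESALREGGLSTAAPK
>ATP5F1A_synthetic synthetic parent scaffold for ATP5F1A marker peptides
MSTELAQVKILGADTSVDLEETGRTGQVESALRVLSIGDGIARDLSVGETANRTGAIVDVPVGEELLGRAGELVSDLKEGGLSTAAPK
>CPS1_synthetic synthetic parent scaffold for CPS1 marker peptides
MSTELAQVKIALGIPLPEIKTGQVESALREGGLSTAAPK
>NDUFAF4_synthetic synthetic parent scaffold for NDUFAF4 marker peptides
MSTELAQVKEQISLYPEVKTGQVESALRIMQEYQLEQKDLSVGETANREGGLSTAAPK
>MAT2A_synthetic synthetic parent scaffold for MAT2A marker peptides
MSTELAQVKTQVTVQYMQDRTGQVESALRYLDEDTIYHLQPSGRDLSVGETANRFVIGGPQGDAGLTGRAGELVSDLKEGGLSTAAPK
>HSP90AB1_synthetic synthetic parent scaffold for HSP90AB1 marker peptides
MSTELAQVKYHTSQSGDEMTSLSEYVSRTGQVESALRHLEINPDHPIVETLRDLSVGETANREGGLSTAAPK
>AHCY_synthetic synthetic parent scaffold for AHCY marker peptides
MSTELAQVKVPAINVNDSVTKTGQVESALRIILLAEGRDLSVGETANREGGLSTAAPK
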