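mirna	gene	evidence
mmu-miR-10a	Cercam	Microarray
mmu-miR-26a	Cercam	Microarray
mmu-miR-26b	Cercam	Microarray
mmu-miR-34a	Cercam	Microarray
mmu-miR-15a	Spsb4	Microarray
mmu-miR-16	Spsb4	Microarray
mmu-miR-24	Spsb4	Microarray
mmu-miR-17	Spsb4	Microarray
mmu-miR-146a	Traf6	Luciferase reporter assay//Western blot
mmu-miR-146a	Irak1	Luciferase reporter assay//Western blot
mmu-miR-155	Socs1	Luciferase reporter assay
mmu-miR-155	Ship1	Western blot
mmu-miR-16	Bcl2	Luciferase reporter assay//qRT-PCR
mmu-miR-15a	Bcl2	Luciferase reporter assay//qRT-PCR
mmu-miR-15a	Ccnd1	Luciferase reporter assay
mmu-miR-29a	Dnmt3a	Luciferase reporter assay//Western blot
mmu-miR-29a	Dnmt3b	Luciferase reporter assay
mmu-miR-29b	Dnmt3a	Luciferase reporter assay
mmu-miR-29b	Dnmt3b	Western blot
mmu-miR-29c	Dnmt3a	qRT-PCR
mmu-miR-29c	Col1a1	Microarray
mmu-miR-22	Hdac1	Luciferase reporter assay//Western blot
mmu-miR-22	Sirt1	Luciferase reporter assay
mmu-miR-24	Chi3l1	Microarray
mmu-miR-26a	Ezh2	Luciferase reporter assay
mmu-miR-26b	Lef1	Luciferase reporter assay//Western blot
mmu-miR-10a	Usf2	Western blot
mmu-miR-10a	Hoxa1	Luciferase reporter assay
mmu-miR-103	Dicer1	Luciferase reporter assay
mmu-miR-106b	Pten	Luciferase reporter assay
mmu-miR-106b	Cdkn1a	Western blot
mmu-miR-126	Vcam1	Luciferase reporter assay
mmu-miR-143	Kras	Luciferase reporter assay//Western blot
mmu-miR-145	Myc	Luciferase reporter assay
mmu-miR-152	Dnmt1	Luciferase reporter assay
mmu-miR-18a	Esr1	Luciferase reporter assay
mmu-miR-192	Zeb2	Microarray
mmu-miR-194	Cdh2	Western blot
mmu-miR-19b	Pten	Luciferase reporter assay
mmu-miR-20a	E2f1	Luciferase reporter assay
mmu-miR-20b	Hif1a	Luciferase reporter assay
mmu-miR-21	Pdcd4	Luciferase reporter assay//Western blot
mmu-miR-223	Stat3	Western blot
mmu-miR-25	Bim	Luciferase reporter assay
mmu-miR-335	Sox4	Luciferase reporter assay
mmu-miR-93	Vegfa	Microarray
mmu-miR-34a	Sirt1	Luciferase reporter assay//Western blot
mmu-miR-34a	Bcl2	Luciferase reporter assay
mmu-let-7b	Myc	Luciferase reporter assay
mmu-miR-9	Nfkb1	Luciferase reporter assay
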