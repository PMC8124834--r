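hallmark	mirna	downregulated
altered DNA damage response	miR-106b	TRUE
altered DNA damage response	miR-125b	FALSE
altered DNA damage response	miR-138	FALSE
altered DNA damage response	miR-182	FALSE
altered DNA damage response	miR-18a	TRUE
altered DNA damage response	miR-192	FALSE
altered DNA damage response	miR-194	TRUE
altered DNA damage response	miR-210	FALSE
altered DNA damage response	miR-215	FALSE
altered DNA damage response	miR-22	TRUE
altered DNA damage response	miR-24	TRUE
altered DNA damage response	miR-34a	FALSE
altered DNA damage response	miR-34b	FALSE
altered DNA damage response	miR-34c	FALSE
altered DNA damage response	miR-421	FALSE
altered DNA damage response	miR-504	FALSE
loss of telomeres	miR-103	TRUE
loss of telomeres	miR-124	FALSE
loss of telomeres	miR-138	FALSE
loss of telomeres	miR-143	TRUE
loss of telomeres	miR-155	TRUE
loss of telomeres	miR-34a	FALSE
loss of telomeres	miR-34b	FALSE
loss of telomeres	miR-34c	FALSE
DNA methylation	miR-127	FALSE
DNA methylation	miR-143	TRUE
DNA methylation	miR-148a	FALSE
DNA methylation	miR-152	TRUE
DNA methylation	miR-29a	TRUE
DNA methylation	miR-29b	TRUE
DNA methylation	miR-29c	TRUE
DNA methylation	miR-34a	FALSE
DNA methylation	miR-34b	FALSE
DNA methylation	miR-34c	FALSE
DNA methylation	miR-9	FALSE
histone modifications	miR-144	FALSE
histone modifications	miR-15a	TRUE
histone modifications	miR-16	TRUE
histone modifications	miR-26a	TRUE
histone modifications	miR-29a	TRUE
histone modifications	miR-29b	TRUE
histone modifications	miR-29c	TRUE
histone modifications	miR-98	FALSE
regulation of splicing	miR-10a	TRUE
regulation of splicing	miR-10b	FALSE
regulation of splicing	miR-125a	FALSE
regulation of splicing	miR-137	FALSE
regulation of splicing	miR-16	TRUE
regulation of splicing	miR-340	FALSE
changes to protein homeostasis	miR-106b	TRUE
changes to protein homeostasis	miR-26b	TRUE
changes to protein homeostasis	miR-301b	FALSE
changes to protein homeostasis	miR-320	FALSE
altered nutrient sensing	miR-106a	FALSE
altered nutrient sensing	miR-126	TRUE
altered nutrient sensing	miR-17	FALSE
altered nutrient sensing	miR-182	FALSE
altered nutrient sensing	miR-190b	FALSE
altered nutrient sensing	miR-19b	TRUE
altered nutrient sensing	miR-206	FALSE
altered nutrient sensing	miR-20a	TRUE
altered nutrient sensing	miR-223	TRUE
altered nutrient sensing	miR-320	FALSE
altered nutrient sensing	miR-470	FALSE
altered nutrient sensing	miR-486	FALSE
altered nutrient sensing	miR-669b	FALSE
altered nutrient sensing	miR-681	FALSE
mitochondrial dysfunction	let-7b	FALSE
mitochondrial dysfunction	miR-106a	FALSE
mitochondrial dysfunction	miR-133b	FALSE
mitochondrial dysfunction	miR-146a	TRUE
mitochondrial dysfunction	miR-181a	FALSE
mitochondrial dysfunction	miR-19b	TRUE
mitochondrial dysfunction	miR-20b	TRUE
mitochondrial dysfunction	miR-221	FALSE
mitochondrial dysfunction	miR-335	TRUE
mitochondrial dysfunction	miR-34a	FALSE
mitochondrial dysfunction	miR-34b	FALSE
mitochondrial dysfunction	miR-34c	FALSE
cellular senescence	let-7a	FALSE
cellular senescence	miR-106a	FALSE
cellular senescence	miR-17	FALSE
cellular senescence	miR-181a	FALSE
cellular senescence	miR-19b	TRUE
cellular senescence	miR-20a	TRUE
cellular senescence	miR-210	FALSE
cellular senescence	miR-217	FALSE
cellular senescence	miR-24	TRUE
cellular senescence	miR-26b	TRUE
cellular senescence	miR-29a	TRUE
cellular senescence	miR-33	FALSE
cellular senescence	miR-34a	FALSE
cellular senescence	miR-34b	FALSE
cellular senescence	miR-34c	FALSE
cellular senescence	miR-499	FALSE
stem cell exhaustion	let-7a	FALSE
stem cell exhaustion	let-7b	FALSE
stem cell exhaustion	miR-106b	TRUE
stem cell exhaustion	miR-25	TRUE
stem cell exhaustion	miR-290	FALSE
stem cell exhaustion	miR-293	FALSE
stem cell exhaustion	miR-294	FALSE
stem cell exhaustion	miR-295	FALSE
stem cell exhaustion	miR-29c	TRUE
stem cell exhaustion	miR-33	FALSE
stem cell exhaustion	miR-489	FALSE
stem cell exhaustion	miR-499	FALSE
stem cell exhaustion	miR-598	FALSE
stem cell exhaustion	miR-93	TRUE
inflammaging	miR-146a	TRUE
inflammaging	miR-155	TRUE
epigenetic alterations (Sirtuins)	miR-135a	FALSE
epigenetic alterations (Sirtuins)	miR-199b	FALSE
epigenetic alterations (Sirtuins)	miR-204	FALSE
epigenetic alterations (Sirtuins)	miR-217	FALSE
epigenetic alterations (Sirtuins)	miR-290	FALSE
epigenetic alterations (Sirtuins)	miR-486	FALSE
epigenetic alterations (Sirtuins)	miR-9	FALSE
stem cell homeostasis	let-7b	FALSE
stem cell homeostasis	miR-16	TRUE
stem cell homeostasis	miR-33	FALSE
stem cell homeostasis	miR-376b	FALSE
stem cell homeostasis	miR-486	FALSE
stem cell homeostasis	miR-489	FALSE
stem cell homeostasis	miR-598	FALSE
stem cell homeostasis	miR-9	FALSE
insulin/IGF1	miR-206	FALSE
insulin/IGF1	miR-320	FALSE
insulin/IGF1	miR-470	FALSE
insulin/IGF1	miR-669b	FALSE
insulin/IGF1	miR-681	FALSE
altered intercellular communication	miR-29a	TRUE
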