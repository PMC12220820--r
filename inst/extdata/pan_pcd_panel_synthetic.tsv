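gene	types	provenance
Acsl4	ferroptosis	crush;contusion;hemisection
Alox5	ferroptosis	crush;contusion;hemisection
Apaf1	apoptosis	crush;contusion;hemisection
Atf3	apoptosis	crush;contusion;hemisection
Atg101	autophagy	crush;contusion;hemisection
Atg5	autophagy	crush;contusion;hemisection
Atg7	autophagy	crush;contusion;hemisection
Bax	apoptosis	crush;contusion;hemisection
Bcl2	apoptosis	crush;contusion;hemisection
Becn1	autophagy	crush;contusion;hemisection
Bid	apoptosis	crush;contusion;hemisection
Casp1	pyroptosis	crush;contusion;hemisection
Casp3	apoptosis	crush;contusion;hemisection
Casp8	apoptosis;necroptosis;pyroptosis	crush;contusion;hemisection
Casp9	apoptosis	crush;contusion;hemisection
Cd68	lysosome_dependent_cell_death	crush;contusion;hemisection
Cd84	pyroptosis	crush;contusion;hemisection
Cdh1	entotic_cell_death	crush;contusion;hemisection
Ctnnb1	entotic_cell_death	crush;contusion;hemisection
Ctsb	lysosome_dependent_cell_death	crush;contusion;hemisection
Ctsl	lysosome_dependent_cell_death	crush;contusion;hemisection
Cycs	apoptosis	crush;contusion;hemisection
Cyld	necroptosis	crush;contusion;hemisection
Fadd	apoptosis;necroptosis	crush;contusion;hemisection
Fas	apoptosis	crush;contusion;hemisection
Fth1	ferroptosis	crush;contusion;hemisection
Gpx4	ferroptosis	crush;contusion;hemisection
Grn	lysosome_dependent_cell_death	crush;contusion;hemisection
Gsdmd	pyroptosis	crush;contusion;hemisection
Il18	pyroptosis	crush;contusion;hemisection
Il1b	pyroptosis	crush;contusion;hemisection
Irf2	pyroptosis	crush;contusion;hemisection
Lamp1	lysosome_dependent_cell_death	crush;contusion;hemisection
Map1lc3b	autophagy	crush;contusion;hemisection
Mcoln1	lysosome_dependent_cell_death	crush;contusion;hemisection
Mlkl	necroptosis	crush;contusion;hemisection
Myc	apoptosis	crush;contusion;hemisection
Myh9	entotic_cell_death	crush;contusion;hemisection
Nlrp3	pyroptosis	crush;contusion;hemisection
Pcdsyn217	pyroptosis	crush;contusion;hemisection
Pcdsyn225	necroptosis	crush;contusion;hemisection
Pcdsyn237	necroptosis	crush;contusion;hemisection
Pcdsyn302	ferroptosis	crush;contusion;hemisection
Pcdsyn365	necroptosis	crush;contusion;hemisection
Pcdsyn495	autophagy	crush;contusion;hemisection
Pcdsyn504	ferroptosis	crush;contusion;hemisection
Pcdsyn514	apoptosis	crush;contusion;hemisection
Pcdsyn533	apoptosis	crush;contusion;hemisection
Pcdsyn584	entotic_cell_death	crush;contusion;hemisection
Pcdsyn663	pyroptosis	crush;contusion;hemisection
Pcdsyn715	autophagy	crush;contusion;hemisection
Ptgs2	ferroptosis	crush;contusion;hemisection
Pycard	pyroptosis	crush;contusion;hemisection
Rhoa	entotic_cell_death	crush;contusion;hemisection
Ripk1	necroptosis	crush;contusion;hemisection
Ripk3	necroptosis	crush;contusion;hemisection
Rock1	entotic_cell_death	crush;contusion;hemisection
Rock2	entotic_cell_death	crush;contusion;hemisection
Slc7a11	ferroptosis	crush;contusion;hemisection
Sqstm1	autophagy	crush;contusion;hemisection
Stat6	apoptosis	crush;contusion;hemisection
Tfrc	ferroptosis	crush;contusion;hemisection
Tnf	apoptosis;necroptosis	crush;contusion;hemisection
Tnfrsf1a	apoptosis;necroptosis	crush;contusion;hemisection
Tradd	necroptosis	crush;contusion;hemisection
Ulk1	autophagy	crush;contusion;hemisection
Xiap	apoptosis	crush;contusion;hemisection
Zbp1	necroptosis	crush;contusion;hemisection
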