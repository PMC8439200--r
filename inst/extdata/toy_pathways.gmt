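linoleic_acid_metabolism	synthetic toy pathway set	M01	M02	M03	M04	M20	M21
fatty_acid_biosynthesis	synthetic toy pathway set	M05	M06	M07	M08	M09	M22
glutamine_glutamate_metabolism	synthetic toy pathway set	M10	M11	M12	M13	M23	M24
glycine_serine_threonine_metabolism	synthetic toy pathway set	M14	M15	M16	M17	M25
aromatic_amino_acid_biosynthesis	synthetic toy pathway set	M18	M19	M26	M27	M28
purine_metabolism	synthetic toy pathway set	M29	M30	M31	M32
tca_cycle	synthetic toy pathway set	M33	M34	M35	M36	M37
bile_acid_biosynthesis	synthetic toy pathway set	M38	M39	M40	M41
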